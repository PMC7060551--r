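# metachrom

Integrative chromatin accessibility analysis of metastatic cancer cell
models and patient cohorts.

## The problem

Metastatic sub-populations of a cancer cell line carry distinctive active
chromatin: differential ATAC-seq peaks, remodeled enhancers and promoters,
and characteristic transcription-factor motifs. `metachrom` implements the
full analysis chain that turns such data into patient-level statements:

- **Peak geometry** — BED/narrowPeak intervals, Tn5 cut-site shifting
  (+5 bp forward / −4 bp reverse), splitting multi-summit peaks at summit
  midpoints, and classifying peaks as *promoter* (overlapping an H3K4me3
  peak that covers a TSS), *enhancer* (overlapping H3K27ac, > 2 kb from
  every expressed-gene TSS) or *unknown*.
- **Differential accessibility** — a self-contained negative-binomial Wald
  engine on median-of-ratios-normalized counts with moderated
  method-of-moments dispersion and Benjamini–Hochberg correction.
- **The metATAC score** — from a signature of robustly differential peaks
  (padj < 5e-5), each patient is scored

  ```
  S = r_Met − r_Par + 1
  ```

  where `r_Met` and `r_Par` are the Pearson correlations of the patient's
  normalized accessibility over the signature peaks with the metastatic
  and parental mean profiles (log2-CPM with prior 5, quantile-normalized).
  Adding 1 keeps scores positive; `S ∈ [−1, 3]`, and patients resembling
  the metastatic profile score above 1.
- **Enhancer–gene linkage** — HiChIP-style anchor pairs are snapped to the
  nearest consensus peak within 2 kb, filtered to links reproduced in all
  replicates, resolved to (gene, enhancer) pairs, and validated with a
  gene-side shuffle null on the fold-change correlation.
- **Motif-cluster enrichment** — TF occurrences (confidence > 0) are
  collapsed into motif clusters; concordant regulatory regions (peaks and
  linked genes changing the same way) form the foreground of an
  upper-tail hypergeometric test against the consensus-peak background.
- **Survival** — z-score merging of expression cohorts, median-split
  stratification, log-rank tests and Efron-tie Cox proportional-hazards
  fits adjusted for clinical covariates, including a per-TF relapse
  screen with motif/hazard concordance flags.
- **Synthetic data** — seeded generators (`fixture_spec()`,
  `gen_genome()`, `gen_counts()`, `gen_links_and_expression()`,
  `gen_motif_bed()`, `gen_cohort()`, `write_fixture()`) produce every
  input with ground truth, so the whole pipeline is testable offline.

See `vignettes/metachrom-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

A complete run on a synthetic fixture — differential accessibility,
signature construction, cohort scoring and survival stratification:

```r
library(metachrom)

spec   <- fixture_spec(seed = 1)
genome <- gen_genome(spec)
cnt    <- gen_counts(spec, genome$peaks)

diff <- nb_differential(cnt$cm, c("metastatic", "parental"))
sig  <- select_signature_peaks(diff, alpha = 5e-5)
norm <- quantile_normalize(cpm_log(cnt$cm))
ss   <- build_signal_sets(norm, c("Par_1", "Par_2"),
                          sprintf("Met_%d", 1:4), sig)

coh    <- gen_cohort(spec, ss)
scores <- score_cohort(coh$signal, ss)
strata <- stratify_median(scores$s)
lr     <- logrank(strata, coh$cohort$clinical$time,
                  coh$cohort$clinical$event)
fit    <- cox_ph(coh$cohort, strata,
                 covariates = c("age", "er", "subtype"))
```

Output:

```
differential peaks (padj < 0.05): 108 of 1000
signature peaks (padj < 5e-5): 100
    patient_id r_par r_met     s
1 patient_0001 0.658 0.654 0.996
2 patient_0002 0.274 0.942 1.667
3 patient_0003 0.184 0.977 1.793
log-rank chi2 = 43.6, p = 4.1e-11
Cox HR (high vs low) = 1.82 [1.49, 2.23], p = 4.7e-09
```

The fixture plants 10% differential peaks at 8-fold; the engine recovers
~100 of them as the signature. Patient 1's profile correlates equally
with both cell states (`s ≈ 1`, ambiguous), patients 2–3 track the
metastatic profile (`s → 2`). Median-split metATAC strata separate
relapse-free survival strongly because the generator couples the latent
metastatic-likeness weight to the hazard (log-HR 0.7 per unit).

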