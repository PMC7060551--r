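---
title: "Methods: models, conventions and design choices in metachrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in metachrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metachrom)
```

# What the pipeline does

`metachrom` implements an integrative epigenomic workflow for comparing a
parental cancer cell line against its metastatic sub-populations and
projecting the resulting chromatin-accessibility signature onto patient
cohorts. The stages are:

1. **Interval geometry** — ATAC-seq peaks, TSS annotations and histone-mark
   peaks live in one coordinate system; peaks are classified as promoters,
   enhancers or unknown.
2. **Differential accessibility** — a negative-binomial Wald test per peak
   over size-factor-normalized counts, BH-corrected.
3. **metATAC scoring** — a signature of robustly differential peaks; every
   patient gets `S = r_Met − r_Par + 1`, the difference of Pearson
   correlations with the metastatic and parental mean profiles.
4. **Enhancer–gene linkage** — chromatin-loop anchor pairs are snapped to
   consensus peaks, filtered for replicate reproducibility, and
   enhancer-to-promoter links are resolved to genes.
5. **Motif-cluster enrichment** — hypergeometric over-representation of TF
   motif clusters in concordant regulatory regions.
6. **Survival** — median-split stratification, log-rank tests and
   covariate-adjusted Cox proportional-hazards fits, per TF if desired.
7. **Synthetic data** — seeded generators produce every input with known
   ground truth, so each stage has a recovery test.

# Coordinate conventions

All intervals are BED-style: 0-based, half-open `[start, end)`. Two
intervals overlap iff they share at least one base; `[0, 10)` and
`[10, 20)` do not. narrowPeak summits are read as offsets from `start`
(column 10, `-1` = absent) and stored as absolute positions.

**Tn5 cut sites.** The transposase inserts with a 9-bp duplication, so read
5′ ends are offset: `+5` bp on the forward strand, `−4` bp from the read
end on the reverse strand. The cut site is the width-1 interval at that
coordinate; for very short reads it may fall outside the read span, which
is accepted (the offset is a property of the 5′ end, not the read body).

**Summit splitting.** Multi-summit peaks are split into one sub-peak per
summit. The boundary between adjacent summits `s_i < s_{i+1}` is
`floor((s_i + s_{i+1}) / 2)`, used as the exclusive end of the left
sub-peak, so the sub-peaks tile the parent exactly and each contains its
own summit. Sub-peaks are renamed `<name>_1 … <name>_k`; the flooring and
the suffix scheme are package conventions (any deterministic choice works,
but one has to be fixed).

**Distances.** The distance between a point `p` (a TSS) and a peak
`[s, e)` is `max(0, s − p, p − e)`: zero when the point lies in the peak,
otherwise the gap to the nearer half-open boundary coordinate. This form
is exactly invariant under coordinate mirroring, which is the symmetry we
test. Ties between an upstream and a downstream TSS at the same gap go to
the smaller coordinate. Anchor-to-peak distances use the analogous
interval-to-interval gap (0 on overlap).

# Peak classification

A peak is a **promoter** when it overlaps an H3K4me3 peak that itself
covers a TSS of an expressed gene; failing that it is an **enhancer** when
it overlaps an H3K27ac peak and its nearest expressed-gene TSS is more
than 2000 bp away (`radius_bp`, exposed); otherwise **unknown**. The
promoter rule takes precedence when both hold — promoter evidence
(H3K4me3 + TSS) is the more specific claim. TSS sets must be restricted
to expressed genes by the caller; the package does not guess expression.

# The differential engine

Counts `y_ij` for peak `i`, sample `j` are modeled as negative binomial.
Normalization uses median-of-ratios size factors: the pseudo-reference is
the per-peak geometric mean over samples (rows with any zero excluded),
and sample `j`'s factor is the median of `y_ij / ref_i`. If no row is
all-nonzero the function stops and points at the pseudo-reference
fallback rather than silently switching estimators.

For the contrast A over B, group means `μ_A`, `μ_B` of normalized counts
are compared with a Wald statistic on
`log2((μ_A + ½) / (μ_B + ½))`; the half-count pseudo-mean stabilizes
near-zero peaks and cancels exactly for identical groups. The variance of
a group mean is `Σ_j (μ/s_j + α μ²) / n²` by the NB variance function.

**Dispersion.** The raw per-peak estimator is method-of-moments pooled
across the two groups. With two to four replicates per group it has one
or two degrees of freedom and is negative for a large fraction of peaks;
flooring those at a small constant makes the Wald test sharply
anti-conservative (empirically ~3× the nominal type-I error at typical
depths). The engine therefore moderates: per-peak estimates are shrunk
toward the across-peak mean dispersion with a prior weight of
`df_prior = 20` residual degrees of freedom, then floored at `1e-4`.
This is the empirical-Bayes idea standard in count-based differential
analysis, reduced to its simplest form (a single common prior rather
than a mean-dispersion trend). Under the package's null simulations the
moderated test holds its size (empirical type-I ≈ 0.05 at nominal 0.05)
while retaining full power on 8-fold planted changes. Peaks with all-zero
counts in both groups are flagged `degenerate` and reported with
`log2fc = 0`, `p = 1`.

The engine is deliberately self-contained and minimal: no fold-change
shrinkage, no independent filtering, no outlier refitting. It is the
default behind a single function so that a different engine can be
swapped in without touching the rest of the pipeline.

# Cohort normalization and the metATAC score

Cohort matrices are transformed with log2 counts-per-million using a
scaled prior (`prior.count = 5`; the per-sample prior is
`5 · L_j / mean(L)`), then quantile-normalized (each column's sorted
values replaced by the across-column mean of sorted values, ties
averaged).

Signature peaks are those with `padj < 5e-5` in the metastatic-versus-
parental contrast — a deliberately stringent threshold so the signature
holds only robustly differential peaks; `0.05` is the conventional level
for within-cell-line analyses, and both are plain arguments. The
parental and metastatic signal sets are arithmetic means of the
normalized replicate columns over the signature peaks; organotropic
variants pass only one sub-population's replicates and reuse the same
code path.

Each patient is scored `S = r_Met − r_Par + 1` with Pearson correlations
over the signature peaks, so `S ∈ [−1, 3]` and scores are positive in
practice; `S` is invariant to positive affine transforms of the patient's
signal, which makes it robust to per-sample scaling. Constant vectors are
an error, not a silent drop: a patient whose signal has no variance
cannot be correlated and should be looked at, not imputed. Median
stratification labels scores strictly above the median `high` and
everything else (including exact ties) `low`; the tie rule is arbitrary
but fixed and documented.

# Linkage

Anchor pairs from each replicate are canonicalized (smaller anchor
first), snapped to the nearest consensus peak within 2000 bp (edge-gap
distance, ties to the smaller start), and pairs with any unassigned
anchor are dropped. Links whose two anchors land on the same peak are
self-links and are dropped — a loop within one peak carries no
enhancer-promoter information at this resolution. Reproducibility is the
intersection of unordered link sets across *all* provided replicates,
generalizing the two-replicate case. Gene links are emitted for
enhancer–promoter links only, one per gene behind the promoter peak (via
the H3K4me3 peaks it overlaps).

The shuffle diagnostic permutes only the gene side of the link table,
preserving the enhancer multiset and per-enhancer degree, so the null
keeps the marginal structure and destroys only the pairing. It is
deterministic given its seed and restores the caller's RNG state.

# Motif enrichment

Occurrences with confidence ≤ 0 are removed at load; TFs missing from
the cluster map are rejected loudly (attribute + warning) rather than
silently pooled. The counting unit is the peak: a cluster is present in
a peak iff any member TF occurs under it, so deep homotypic runs do not
inflate counts. The foreground is the set of significantly differential
peaks whose direction matches the requested one *and* which are linked
(as enhancer, or as promoter) to at least one significantly
differential gene moving the same way — the concordance rule. The test
is the upper-tail hypergeometric (over-representation); gained and lost
foregrounds are tested separately, and the BH family is all clusters
tested within one (contrast, direction) run. Significant clusters are
re-expanded to their member TFs for cross-contrast comparisons.

# Survival

Expression cohorts from different batches are merged after per-dataset,
per-gene z-scoring (`n − 1` convention); genes constant within a dataset
become `NA` with a warning. The log-rank test is the standard two-group
O−E/V statistic with a 1-df chi-square reference. Cox fits use the
partial likelihood with **Efron** tie handling (the common default; the
alternatives differ only at tied event times) and report the exposure
hazard ratio with a Wald p-value and a 95% Wald CI. Categorical
covariates are released with the most frequent category as reference;
fits require at least as many events as coefficients, and suspected
complete separation (diverging exposure coefficient) is an error with a
message rather than a quietly enormous HR. Site-specific analyses use
the event indicator for that site; relapse at another site is treated
as censoring at that time — an assumption of this package, stated here
because the data do not decide it. The per-TF screen median-splits each
TF, runs both tests, BH-adjusts across the screened TFs and, when motif
directions are supplied, flags concordance (gained with HR > 1, lost
with HR < 1).

# The synthetic generators

The generators produce every input the pipeline consumes, with ground
truth, as pure functions of `(spec, seed)` — identical bytes on re-run,
which is itself a test. Defaults encode a typical cell-line design: two
parental and four metastatic replicates, ~1000 consensus peaks on a toy
two-chromosome genome, 10% planted 8-fold accessibility changes, 500
reproducible loops with coupling slope 1 and noise 0.5 (log2 units), a
planted motif cluster at 80% foreground / 10% background occurrence, and
a 500-patient cohort whose latent metastatic-likeness `w ~ Uniform(0,1)`
drives both the accessibility profile (`(1−w)·parental + w·metastatic`
plus Gaussian noise, sd 0.5) and an exponential relapse hazard with
log-HR 0.7 per unit `w` over a baseline of 0.02 events/month, censored
uniformly on 36–120 months. The baseline and censoring window were
chosen once to give a realistic ~60% event fraction; TF panels include
two planted factors tracking `w` (one up, one down) and three null
factors.

Construction guarantees worth knowing when reading the tests: peaks are
spaced ≥ 4 kb apart, so enhancer-class peaks are automatically > 2 kb
from every TSS and anchor jitter (≤ 500 bp) can never re-assign an
anchor to a neighboring peak; spurious anchor pairs are drawn from
disjoint peak pools per replicate, so the reproducibility filter must
remove them all; genes regulated by several enhancers draw all their
enhancers from one fold-change class, so expression tracks each of its
links without attenuation.

**What the generators do not emulate** — and hence what passing tests do
not establish about real data: per-peak dispersion variation (dispersion
is shared within a fixture), GC/mappability biases, copy-number effects
on accessibility, correlated noise across patients, informative
censoring, and any sequence-level realism. The generators validate the
statistical machinery, not the biology.

# Problem sizes and runtime choices

Unit tests run on 30–300-interval fixtures; oracle-equivalence checks
use 1000-interval sets against brute-force scans, 1000 random p-value
vectors against an independent BH step-up, and exhaustive enumeration of
hypergeometric draws up to `N = 12`. Calibration runs use 1000 peaks
(six samples), 50 Cox fits of 500 patients for CI coverage, one fit of
1000 patients for HR recovery, and 20 independent 500-patient cohorts
for log-rank power. These sizes give stable Monte-Carlo estimates while
keeping the whole suite in the tens of seconds.

# Known limitations

- The differential engine tests each peak marginally; no sharing of
  fold-change information across peaks, no trend on dispersion.
- `quantile_normalize` and `cpm_log` delegate to limma and edgeR; exact
  numerical parity with other implementations of these transforms is not
  claimed.
- Signature scoring requires complete patient vectors over the signature
  peaks; there is no imputation by design.
- The hypergeometric model treats peaks as exchangeable; peak length and
  GC content are not covariates of the null.
- Site-specific survival treats other-site relapse as censoring, which
  understates competing risks when they are strong.
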