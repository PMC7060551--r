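#' Synthetic fixture specification
#'
#' Collects every tunable of the seeded generators that emulate the
#' pipeline's inputs: a toy genome of non-overlapping peaks with known
#' promoter/enhancer/unknown classes, negative-binomial peak counts with
#' planted group fold changes, replicate anchor pairs coupling enhancer
#' accessibility to gene expression, motif occurrences with a planted
#' enriched cluster, and a patient cohort whose relapse hazard depends on
#' a latent metastatic-likeness weight `w`.
#'
#' Defaults encode a typical cell-line comparison design: two parental and
#' four metastatic replicates (two sub-populations of two), ~1000 consensus
#' peaks, 8-fold planted accessibility changes, 500 reproducible loops
#' with coupling `beta = 1` and noise `sigma = 0.5`, and a 500-patient
#' cohort with log-hazard 0.7 per unit `w`.
#'
#' @param seed integer seed; all generators are pure functions of
#'   `(spec, seed)`.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param n_peaks total consensus peaks.
#' @param frac_promoter,frac_enhancer fractions of peak classes (the rest
#'   are `unknown`).
#' @param nb_mean,nb_dispersion negative-binomial count parameters shared
#'   across peaks.
#' @param frac_differential fraction of peaks with a planted fold change.
#' @param log2fc_magnitude magnitude of planted log2 fold changes.
#' @param n_par,n_met parental / metastatic replicate counts.
#' @param n_links number of true enhancer-promoter links.
#' @param linkage_beta,linkage_sigma coupling slope and noise of gene
#'   log2FC on linked-enhancer log2FC.
#' @param spurious_frac fraction of extra replicate-unique anchor pairs.
#' @param anchor_jitter max anchor displacement from its peak (bp).
#' @param fg_rate,bg_rate planted-cluster occurrence rates in foreground /
#'   background peaks.
#' @param n_decoy_clusters decoy clusters occurring uniformly.
#' @param zero_conf_frac fraction of motif records with confidence 0
#'   (must be filtered on load).
#' @param n_patients cohort size.
#' @param cohort_noise sd of patient signal noise (log2 units).
#' @param baseline_hazard baseline event rate per month at `w = 0`.
#' @param log_hr log hazard ratio per unit `w`.
#' @param censor_range uniform censoring window (months).
#' @return list of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L,
                         chrom_sizes = c(chrS1 = 30e6, chrS2 = 20e6),
                         n_peaks = 1000L,
                         frac_promoter = 0.3, frac_enhancer = 0.5,
                         nb_mean = 100, nb_dispersion = 0.05,
                         frac_differential = 0.1, log2fc_magnitude = 3,
                         n_par = 2L, n_met = 4L,
                         n_links = 500L, linkage_beta = 1,
                         linkage_sigma = 0.5, spurious_frac = 0.3,
                         anchor_jitter = 500L,
                         fg_rate = 0.8, bg_rate = 0.1,
                         n_decoy_clusters = 10L, zero_conf_frac = 0.05,
                         n_patients = 500L, cohort_noise = 0.5,
                         baseline_hazard = 0.02, log_hr = 0.7,
                         censor_range = c(36, 120)) {
  fr <- c(frac_promoter, frac_enhancer, frac_differential, fg_rate, bg_rate,
          spurious_frac, zero_conf_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions and rates must lie in [0, 1]")
  if (frac_promoter + frac_enhancer > 1)
    stop("frac_promoter + frac_enhancer must be <= 1")
  if (nb_mean <= 0 || nb_dispersion <= 0 || baseline_hazard <= 0)
    stop("rates must be > 0")
  spec <- list(seed = as.integer(seed), chrom_sizes = chrom_sizes,
               n_peaks = as.integer(n_peaks), frac_promoter = frac_promoter,
               frac_enhancer = frac_enhancer, nb_mean = nb_mean,
               nb_dispersion = nb_dispersion,
               frac_differential = frac_differential,
               log2fc_magnitude = log2fc_magnitude,
               n_par = as.integer(n_par), n_met = as.integer(n_met),
               n_links = as.integer(n_links), linkage_beta = linkage_beta,
               linkage_sigma = linkage_sigma, spurious_frac = spurious_frac,
               anchor_jitter = as.integer(anchor_jitter),
               fg_rate = fg_rate, bg_rate = bg_rate,
               n_decoy_clusters = as.integer(n_decoy_clusters),
               zero_conf_frac = zero_conf_frac,
               n_patients = as.integer(n_patients),
               cohort_noise = cohort_noise,
               baseline_hazard = baseline_hazard, log_hr = log_hr,
               censor_range = censor_range)
  class(spec) <- "FixtureSpec"
  spec
}

#' Generate the toy genome
#'
#' Places non-overlapping peaks with >= 4 kb gaps.  Promoter-class peaks
#' carry a TSS at their center and an H3K4me3 peak covering them;
#' enhancer-class peaks are covered by an H3K27ac peak and, by the spacing
#' guarantee, lie > 2 kb from every TSS; unknown peaks carry no mark.
#'
#' @param spec a [fixture_spec()].
#' @return list: `peaks`, `tss`, `h3k27ac`, `h3k4me3` ([peak_set()]s) and
#'   `truth` (data frame `peak_id`, `cls`, `gene_id`).
#' @export
gen_genome <- function(spec) {
  with_seed(spec$seed, {
    chroms <- names(spec$chrom_sizes)
    n_per <- table(factor(sample(chroms, spec$n_peaks, replace = TRUE,
                                 prob = spec$chrom_sizes /
                                   sum(spec$chrom_sizes)),
                          levels = chroms))
    chrom <- integer(0)
    all_chrom <- character(0); all_start <- integer(0); all_end <- integer(0)
    for (ch in chroms) {
      k <- n_per[[ch]]
      if (k == 0L) next
      widths <- sample(300:800, k, replace = TRUE)
      gaps <- sample(4000:12000, k, replace = TRUE)
      starts <- 10000L + cumsum(gaps) + cumsum(c(0L, widths[-k]))
      ends <- starts + widths
      if (ends[k] > spec$chrom_sizes[[ch]])
        stop(sprintf("chromosome %s too small for %d peaks", ch, k))
      all_chrom <- c(all_chrom, rep(ch, k))
      all_start <- c(all_start, starts)
      all_end <- c(all_end, ends)
    }
    n <- length(all_start)
    cls <- sample(rep(c("promoter", "enhancer", "unknown"),
                      times = c(round(spec$frac_promoter * n),
                                round(spec$frac_enhancer * n),
                                n - round(spec$frac_promoter * n) -
                                  round(spec$frac_enhancer * n))))
    peaks <- peak_set(all_chrom, all_start, all_end,
                      name = sprintf("peak_%04d", seq_len(n)))
    # normalization sorted the peaks; recover class per sorted name
    cls <- cls[match(peaks$name, sprintf("peak_%04d", seq_len(n)))]
    is_prom <- cls == "promoter"
    gene_id <- rep(NA_character_, n)
    gene_id[is_prom] <- sprintf("gene_%04d", seq_len(sum(is_prom)))
    tss_pos <- as.integer((peaks$start[is_prom] + peaks$end[is_prom]) %/% 2)
    tss <- peak_set(peaks$chrom[is_prom], tss_pos, tss_pos + 1L,
                    name = gene_id[is_prom])
    h3k4me3 <- peak_set(peaks$chrom[is_prom],
                        pmax(0L, peaks$start[is_prom] - 200L),
                        peaks$end[is_prom] + 200L,
                        name = sprintf("k4_%04d", seq_len(sum(is_prom))))
    is_enh <- cls == "enhancer"
    h3k27ac <- peak_set(peaks$chrom[is_enh],
                        pmax(0L, peaks$start[is_enh] - 100L),
                        peaks$end[is_enh] + 100L,
                        name = sprintf("k27_%04d", seq_len(sum(is_enh))))
    list(peaks = peaks, tss = tss, h3k27ac = h3k27ac, h3k4me3 = h3k4me3,
         truth = data.frame(peak_id = peaks$name, cls = cls,
                            gene_id = gene_id, stringsAsFactors = FALSE))
  })
}

#' Generate negative-binomial peak counts with planted fold changes
#'
#' Counts are NB with shared dispersion; per-sample library factors are
#' drawn uniformly in `[0.7, 1.3]`.  A `frac_differential` subset of peaks
#' gets its mean multiplied by `2^(+-log2fc_magnitude)` (random sign) in
#' the metastatic group.
#'
#' @param spec a [fixture_spec()].
#' @param peaks a [peak_set()].
#' @param seed_offset added to `spec$seed` so successive stages use
#'   distinct streams (default 1).
#' @return list: `cm` (a [count_matrix()] with groups `parental` /
#'   `metastatic`), `truth` (data frame `peak_id`, `true_lfc`), and
#'   `lib_factors`.
#' @export
gen_counts <- function(spec, peaks, seed_offset = 1L) {
  with_seed(spec$seed + seed_offset, {
    n <- nrow(peaks)
    n_samp <- spec$n_par + spec$n_met
    group <- c(rep("parental", spec$n_par), rep("metastatic", spec$n_met))
    sample_id <- c(sprintf("Par_%d", seq_len(spec$n_par)),
                   sprintf("Met_%d", seq_len(spec$n_met)))
    lib <- stats::runif(n_samp, 0.7, 1.3)
    n_diff <- round(spec$frac_differential * n)
    diff_idx <- sort(sample.int(n, n_diff))
    sgn <- sample(c(-1, 1), n_diff, replace = TRUE)
    true_lfc <- numeric(n)
    true_lfc[diff_idx] <- sgn * spec$log2fc_magnitude
    mu_base <- rep(spec$nb_mean, n)
    counts <- matrix(0L, n, n_samp, dimnames = list(peaks$name, sample_id))
    for (j in seq_len(n_samp)) {
      mu_j <- mu_base * lib[j]
      if (group[j] == "metastatic") mu_j <- mu_j * 2^true_lfc
      counts[, j] <- stats::rnbinom(n, mu = mu_j,
                                    size = 1 / spec$nb_dispersion)
    }
    list(cm = count_matrix(counts, group = group),
         truth = data.frame(peak_id = peaks$name, true_lfc = true_lfc,
                            stringsAsFactors = FALSE),
         lib_factors = stats::setNames(lib, sample_id))
  })
}

#' Generate anchor pairs and coupled gene expression
#'
#' True enhancer-promoter links are drawn between enhancer-class peaks and
#' gene promoters; each linked gene's expression log2FC is
#' `beta * (enhancer accessibility log2FC) + Normal(0, sigma)` (unlinked
#' genes get pure noise).  Every true link appears in both replicates with
#' anchors jittered within `anchor_jitter` bp of their peaks; a
#' `spurious_frac` of additional replicate-unique pairs is added per
#' replicate (these must be removed by the reproducibility filter).
#'
#' @param spec a [fixture_spec()].
#' @param genome output of [gen_genome()].
#' @param peak_lfc named vector, peak id -> accessibility log2FC (e.g. the
#'   `true_lfc` truth of [gen_counts()]).
#' @param seed_offset RNG stream offset (default 2).
#' @return list: `reps` (two `AnchorPairSet`s), `gene_fc`, `enhancer_fc`
#'   (named vectors), `true_links` (data frame `gene_id`,
#'   `enhancer_peak_id`), `spurious` (per-replicate spurious peak pairs).
#' @export
gen_links_and_expression <- function(spec, genome, peak_lfc,
                                     seed_offset = 2L) {
  with_seed(spec$seed + seed_offset, {
    truth <- genome$truth
    enh <- truth$peak_id[truth$cls == "enhancer"]
    prom <- truth$peak_id[truth$cls == "promoter"]
    if (length(enh) < 2L || length(prom) < 2L)
      stop("need at least 2 enhancer and 2 promoter peaks")
    n_links <- min(spec$n_links, length(enh) * length(prom))
    link_prom <- sample(prom, n_links, replace = TRUE)
    # a gene regulated by several enhancers draws them all from one
    # fold-change class, so its expression tracks each of its links
    enh_fc_all <- peak_lfc[enh]
    link_enh <- character(n_links)
    for (g in unique(link_prom)) {
      idx <- which(link_prom == g)
      seed_enh <- enh[sample.int(length(enh), 1L)]
      pool <- enh[enh_fc_all == peak_lfc[[seed_enh]]]
      link_enh[idx] <- pool[sample.int(length(pool), length(idx),
                                       replace = length(idx) > length(pool))]
    }
    gene_of <- stats::setNames(truth$gene_id, truth$peak_id)
    true_links <- unique(data.frame(gene_id = unname(gene_of[link_prom]),
                                    enhancer_peak_id = link_enh,
                                    stringsAsFactors = FALSE))
    # gene expression coupled to the linked enhancer accessibility change;
    # genes hit by several enhancers average their signals
    genes <- truth$gene_id[!is.na(truth$gene_id)]
    enh_fc <- peak_lfc[true_links$enhancer_peak_id]
    sig <- tapply(enh_fc, true_links$gene_id, mean)
    gene_fc <- stats::setNames(stats::rnorm(length(genes), 0,
                                            spec$linkage_sigma), genes)
    gene_fc[names(sig)] <- spec$linkage_beta * sig +
      stats::rnorm(length(sig), 0, spec$linkage_sigma)
    enhancer_fc <- peak_lfc[enh]
    # anchors per replicate: jittered spans around the two linked peaks
    pk <- genome$peaks
    span <- function(ids) {
      i <- match(ids, pk$name)
      data.frame(chrom = pk$chrom[i], start = pk$start[i], end = pk$end[i])
    }
    jitter_pairs <- function(a, b) {
      ja <- sample(-spec$anchor_jitter:spec$anchor_jitter, nrow(a), TRUE)
      jb <- sample(-spec$anchor_jitter:spec$anchor_jitter, nrow(b), TRUE)
      anchor_pair_set(a$chrom, pmax(0L, a$start + ja), a$end + ja,
                      b$chrom, pmax(0L, b$start + jb), b$end + jb)
    }
    a_span <- span(link_enh); b_span <- span(link_prom)
    n_spur <- round(spec$spurious_frac * n_links)
    # spurious pairs: unknown-class anchors, disjoint pools per replicate
    unk <- truth$peak_id[truth$cls == "unknown"]
    spur_pool <- sample(unk)
    half <- length(spur_pool) %/% 2
    make_spur <- function(pool, k) {
      if (k == 0L || length(pool) < 2L)
        return(data.frame(peakA = character(0), peakB = character(0)))
      a <- sample(pool, k, replace = TRUE)
      b <- sample(pool, k, replace = TRUE)
      keep <- a != b
      data.frame(peakA = a[keep], peakB = b[keep], stringsAsFactors = FALSE)
    }
    spur1 <- make_spur(spur_pool[seq_len(half)], n_spur)
    spur2 <- make_spur(spur_pool[(half + 1):length(spur_pool)], n_spur)
    rep_of <- function(spur) {
      sa <- span(c(link_enh, spur$peakA))
      sb <- span(c(link_prom, spur$peakB))
      ap <- jitter_pairs(sa, sb)
      ap
    }
    rep1 <- rep_of(spur1); rep1$replicate_id <- "rep1"
    rep2 <- rep_of(spur2); rep2$replicate_id <- "rep2"
    list(reps = list(rep1, rep2), gene_fc = gene_fc,
         enhancer_fc = enhancer_fc, true_links = true_links,
         spurious = list(rep1 = spur1, rep2 = spur2))
  })
}

#' Generate motif occurrences with a planted enriched cluster
#'
#' The planted cluster occurs under `fg_rate` of the given foreground
#' peaks and `bg_rate` of all other peaks; decoy clusters occur uniformly
#' at `bg_rate`.  A `zero_conf_frac` of additional records carries
#' confidence 0 and must disappear on load.
#'
#' @param spec a [fixture_spec()].
#' @param peaks a [peak_set()].
#' @param foreground character vector of true-foreground peak ids.
#' @param seed_offset RNG stream offset (default 3).
#' @return list: `occurrences` (data frame writable as BED-like TSV),
#'   `cmap` (a [cluster_map()]), `planted_cluster` (its id).
#' @export
gen_motif_bed <- function(spec, peaks, foreground, seed_offset = 3L) {
  with_seed(spec$seed + seed_offset, {
    planted_tfs <- c("TF_P1", "TF_P2")
    decoy_tfs <- sprintf("TF_D%02d", seq_len(spec$n_decoy_clusters))
    cmap <- cluster_map(c(planted_tfs, decoy_tfs),
                        c("cluster_planted", "cluster_planted",
                          sprintf("cluster_d%02d",
                                  seq_len(spec$n_decoy_clusters))),
                        c("planted-family", "planted-family",
                          sprintf("decoy-family-%02d",
                                  seq_len(spec$n_decoy_clusters))))
    occ <- list()
    emit <- function(idx, tf, conf) {
      if (length(idx) == 0L) return(NULL)
      pos <- peaks$start[idx] +
        vapply(idx, function(i)
          sample.int(max(1L, peaks$end[i] - peaks$start[i] - 10L), 1L),
          integer(1))
      data.frame(chrom = peaks$chrom[idx], start = pos, end = pos + 10L,
                 tf_name = tf, confidence = conf, strand = "+",
                 stringsAsFactors = FALSE)
    }
    is_fg <- peaks$name %in% foreground
    fg_idx <- which(is_fg); bg_idx <- which(!is_fg)
    hit_fg <- fg_idx[stats::runif(length(fg_idx)) < spec$fg_rate]
    hit_bg <- bg_idx[stats::runif(length(bg_idx)) < spec$bg_rate]
    for (idx in list(hit_fg, hit_bg)) {
      tf <- sample(planted_tfs, length(idx), replace = TRUE)
      occ[[length(occ) + 1L]] <- emit(idx, tf, stats::runif(length(idx), 0.1, 1))
    }
    for (d in seq_len(spec$n_decoy_clusters)) {
      idx <- which(stats::runif(nrow(peaks)) < spec$bg_rate)
      occ[[length(occ) + 1L]] <- emit(idx, decoy_tfs[d],
                                      stats::runif(length(idx), 0.1, 1))
    }
    res <- do.call(rbind, occ)
    n_zero <- round(spec$zero_conf_frac * nrow(res))
    if (n_zero > 0L) {
      idx <- sample.int(nrow(peaks), n_zero, replace = TRUE)
      zr <- emit(idx, sample(c(planted_tfs, decoy_tfs), n_zero, TRUE), 0)
      res <- rbind(res, zr)
    }
    res <- res[order(res$chrom, res$start, res$tf_name), , drop = FALSE]
    rownames(res) <- NULL
    list(occurrences = res, cmap = cmap, planted_cluster = "cluster_planted")
  })
}

#' Generate a patient cohort with latent metastatic-likeness
#'
#' Each patient draws `w ~ Uniform(0, 1)`; their accessibility over the
#' signature peaks is `(1 - w) * par_signal + w * met_signal` plus
#' Gaussian noise.  Event times are exponential with log-hazard
#' `log(baseline_hazard) + log_hr * w`, independently censored uniformly
#' over `censor_range`.  A small TF expression panel is included: planted
#' TFs track `w` (positively = `gained` direction, negatively = `lost`),
#' null TFs are pure noise.  Clinical covariates (age, ER/PR/HER2 status,
#' subtype, stage, differentiation, chemotherapy) are drawn with mild
#' correlation between ER-negativity and `w`.
#'
#' @param spec a [fixture_spec()].
#' @param sig a `SignalSet` from [build_signal_sets()].
#' @param seed_offset RNG stream offset (default 4).
#' @return list: `signal` (patients x signature peaks), `w`, `cohort` (a
#'   [cohort_table()] with the TF panel as expression), `tf_truth`
#'   (named direction vector for the planted TFs).
#' @export
gen_cohort <- function(spec, sig, seed_offset = 4L) {
  with_seed(spec$seed + seed_offset, {
    n <- spec$n_patients
    ids <- sprintf("patient_%04d", seq_len(n))
    w <- stats::runif(n)
    base <- outer(1 - w, sig$par_signal) + outer(w, sig$met_signal)
    signal <- base + matrix(stats::rnorm(n * length(sig$peak_ids), 0,
                                         spec$cohort_noise),
                            n, length(sig$peak_ids))
    dimnames(signal) <- list(ids, sig$peak_ids)
    rate <- spec$baseline_hazard * exp(spec$log_hr * w)
    t_event <- stats::rexp(n, rate)
    t_cens <- stats::runif(n, spec$censor_range[1], spec$censor_range[2])
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    # site of relapse among events: high-w relapses skew to lung/brain
    site <- rep(NA_character_, n)
    ev <- which(event == 1L)
    site[ev] <- ifelse(stats::runif(length(ev)) < 0.4 + 0.3 * w[ev],
                       ifelse(stats::runif(length(ev)) < 0.5, "lung", "brain"),
                       "other")
    tf_truth <- c(TF_GAIN = "gained", TF_LOSS = "lost")
    expr <- cbind(
      TF_GAIN = 1.5 * w + stats::rnorm(n, 0, 0.5),
      TF_LOSS = -1.5 * w + stats::rnorm(n, 0, 0.5),
      TF_NULL1 = stats::rnorm(n), TF_NULL2 = stats::rnorm(n),
      TF_NULL3 = stats::rnorm(n))
    rownames(expr) <- ids
    er <- stats::rbinom(n, 1, pmin(0.95, pmax(0.05, 0.8 - 0.4 * w)))
    clinical <- data.frame(
      patient_id = ids, time = time, event = event,
      event_any = event,
      event_lung = as.integer(event == 1L & site == "lung"),
      event_brain = as.integer(event == 1L & site == "brain"),
      age = round(stats::rnorm(n, 58, 12)),
      er = er, pr = stats::rbinom(n, 1, 0.6), her2 = stats::rbinom(n, 1, 0.2),
      subtype = sample(c("lumA", "lumB", "her2e", "basal"), n, TRUE,
                       prob = c(0.4, 0.25, 0.15, 0.2)),
      stage = sample(c("I", "II", "III"), n, TRUE, prob = c(0.3, 0.5, 0.2)),
      differentiation = sample(1:3, n, TRUE),
      chemo = stats::rbinom(n, 1, 0.5),
      stringsAsFactors = FALSE)
    list(signal = signal, w = w,
         cohort = cohort_table(clinical, expr),
         tf_truth = tf_truth)
  })
}

#' Write a complete fixture to disk
#'
#' Materializes every generated input in its plain-text exchange format:
#' peaks as narrowPeak, TSS/marks as BED, anchor pairs as BEDPE (one file
#' per replicate), counts / motif occurrences / cluster map / truth
#' tables / cohort tables as TSV.  Byte-identical across runs for a fixed
#' spec.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- gen_genome(spec)
  counts <- gen_counts(spec, genome$peaks)
  lfc <- stats::setNames(counts$truth$true_lfc, counts$truth$peak_id)
  links <- gen_links_and_expression(spec, genome, lfc)
  fg_truth <- counts$truth$peak_id[counts$truth$true_lfc > 0]
  motifs <- gen_motif_bed(spec, genome$peaks, fg_truth)
  f <- function(...) file.path(dir, sprintf(...))
  tsv <- function(x, path, ...) utils::write.table(
    x, path, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  write_narrowpeak(genome$peaks, f("peaks.narrowPeak"))
  write_bed(genome$tss, f("tss.bed"))
  write_bed(genome$h3k27ac, f("h3k27ac.bed"))
  write_bed(genome$h3k4me3, f("h3k4me3.bed"))
  tsv(genome$truth, f("peak_truth.tsv"))
  cnt <- data.frame(peak_id = rownames(counts$cm$counts),
                    counts$cm$counts, check.names = FALSE)
  tsv(cnt, f("counts.tsv"))
  tsv(counts$cm$sample_meta, f("sample_meta.tsv"))
  tsv(counts$truth, f("count_truth.tsv"))
  for (i in seq_along(links$reps)) {
    p <- links$reps[[i]]$pairs
    utils::write.table(p, f("anchors_rep%d.bedpe", i), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  tsv(links$true_links, f("link_truth.tsv"))
  tsv(data.frame(gene_id = names(links$gene_fc),
                 log2fc = unname(links$gene_fc)), f("gene_fc.tsv"))
  utils::write.table(motifs$occurrences, f("motifs.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  tsv(motifs$cmap, f("cluster_map.tsv"))
  invisible(list.files(dir, full.names = TRUE))
}
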