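#' Construct a peak-by-sample count matrix
#'
#' @param counts integer matrix, peaks in rows (rownames = peak ids),
#'   samples in columns (colnames = sample ids); all entries `>= 0`.
#' @param group character vector of group labels, one per sample.
#' @param replicate optional replicate ids (defaults to within-group index).
#' @return list of class `CountMatrix` with elements `counts` and
#'   `sample_meta` (data frame: `sample_id`, `group`, `replicate`).
#' @export
count_matrix <- function(counts, group, replicate = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs peak rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("peak and sample ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(group) != ncol(counts))
    stop("one group label per sample required")
  group <- as.character(group)
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(group), group, FUN = seq_along)
  meta <- data.frame(sample_id = colnames(counts), group = group,
                     replicate = as.character(replicate),
                     stringsAsFactors = FALSE)
  structure(list(counts = counts, sample_meta = meta),
            class = "CountMatrix")
}

#' Count cut sites falling within peaks
#'
#' Entry (i, j) is the number of sample-j cut sites whose position lies in
#' peak i's half-open span.  Sites outside every peak are dropped; a site
#' inside several overlapping peaks increments each of them.
#'
#' @param cut_sites named list (one element per sample) of width-1
#'   [peak_set()]s of Tn5 cut sites.
#' @param peaks a [peak_set()].
#' @param group group label per sample (same order as `cut_sites`).
#' @return a [count_matrix()].
#' @export
count_in_peaks <- function(cut_sites, peaks, group) {
  stop_not_peakset(peaks, "peaks")
  if (is.null(names(cut_sites))) stop("cut_sites must be a named list")
  gr_peaks <- ps_granges(peaks)
  counts <- vapply(cut_sites, function(cs) {
    stop_not_peakset(cs, "cut_sites[[i]]")
    GenomicRanges::countOverlaps(gr_peaks, ps_granges(cs))
  }, integer(nrow(peaks)))
  counts <- matrix(counts, nrow = nrow(peaks),
                   dimnames = list(peaks$name, names(cut_sites)))
  count_matrix(counts, group = group)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: a pseudo-reference is the per-peak
#' geometric mean across samples (rows containing any zero are excluded);
#' the factor for sample j is the median over peaks of
#' `count_ij / reference_i`.
#'
#' @param cm a [count_matrix()] (or bare matrix).
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  y <- if (inherits(cm, "CountMatrix")) cm$counts else as.matrix(cm)
  keep <- rowSums(y == 0) == 0
  if (!any(keep))
    stop("no peak has nonzero counts in all samples; ",
         "a pseudo-reference over nonzero peaks would be required")
  ly <- log(y[keep, , drop = FALSE])
  ref <- rowMeans(ly)                     # log geometric mean
  sf <- apply(ly, 2, function(col) exp(stats::median(col - ref)))
  stats::setNames(sf, colnames(y))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' log2 counts per million with scaled prior count
#'
#' Per-sample prior `pi_j = prior * L_j / mean(L)` is added before scaling,
#' so that `value = log2((count + pi_j) / (L_j + 2 * pi_j) * 1e6)` — the
#' transform used for cohort-level accessibility matrices.
#'
#' @param cm a [count_matrix()] or bare count matrix.
#' @param prior prior count (default 5).
#' @return numeric matrix of log2-CPM values, same dimnames.
#' @export
cpm_log <- function(cm, prior = 5) {
  y <- if (inherits(cm, "CountMatrix")) cm$counts else as.matrix(cm)
  if (any(colSums(y) <= 0)) stop("every sample needs a positive library size")
  edgeR::cpm(y, log = TRUE, prior.count = prior)
}

#' Quantile normalization across samples
#'
#' Each column's sorted values are replaced by the across-column mean of
#' sorted values, preserving within-column ranks; ties receive the mean of
#' the tied target values.
#'
#' @param m numeric matrix with at least two columns.
#' @return matrix of the same shape; all columns share one value multiset.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("quantile normalization needs >= 2 columns")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}
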