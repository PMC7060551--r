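#' Select signature peaks from a differential result
#'
#' Peaks with `padj < alpha` form the accessibility signature used for
#' cohort scoring; order is preserved.  The stringent default (5e-5) keeps
#' only robustly differential peaks; 0.05 is typical for within-cell-line
#' analyses.
#'
#' @param diff a `DifferentialResult` (see [nb_differential()]).
#' @param alpha adjusted-p-value cutoff (default `5e-5`).
#' @return character vector of peak ids.
#' @export
select_signature_peaks <- function(diff, alpha = 5e-5) {
  if (!all(c("peak_id", "padj") %in% names(diff)))
    stop("`diff` must have peak_id and padj columns")
  ids <- diff$peak_id[diff$padj < alpha]
  if (length(ids) < 3L)
    stop(sprintf("only %d peaks pass padj < %g; ", length(ids), alpha),
         "at least 3 are needed for correlation scoring")
  ids
}

#' Build parental / metastatic signal sets
#'
#' Averages normalized signal across the listed replicate columns,
#' restricted to the signature peaks.  For organotropic variants, pass only
#' the replicates of one metastatic sub-population as `met_ids`.
#'
#' @param norm normalized matrix (peaks x samples), typically
#'   [cpm_log()] followed by [quantile_normalize()].
#' @param par_ids,met_ids column names of parental / metastatic replicates.
#' @param signature_peaks peak ids (rows of `norm`) in the signature.
#' @return list of class `SignalSet`: `peak_ids`, `par_signal`,
#'   `met_signal`.
#' @export
build_signal_sets <- function(norm, par_ids, met_ids, signature_peaks) {
  norm <- as.matrix(norm)
  missing_s <- setdiff(c(par_ids, met_ids), colnames(norm))
  if (length(missing_s) > 0L)
    stop("replicate columns absent from matrix: ",
         paste(missing_s, collapse = ", "))
  missing_p <- setdiff(signature_peaks, rownames(norm))
  if (length(missing_p) > 0L)
    stop("signature peaks absent from matrix: ",
         paste(utils::head(missing_p, 5), collapse = ", "))
  if (length(signature_peaks) < 3L) stop("need >= 3 signature peaks")
  sub <- norm[signature_peaks, , drop = FALSE]
  structure(list(peak_ids = signature_peaks,
                 par_signal = rowMeans(sub[, par_ids, drop = FALSE]),
                 met_signal = rowMeans(sub[, met_ids, drop = FALSE])),
            class = "SignalSet")
}

#' metATAC score for one patient
#'
#' Pearson-correlates the patient's accessibility over the signature peaks
#' with the parental and metastatic mean profiles and reports
#' `s = r_met - r_par + 1` (the +1 keeps scores positive, so
#' `s` lies in `[-1, 3]`); patients resembling the metastatic profile score
#' above 1.
#'
#' @param patient_signal numeric vector aligned to `sig$peak_ids`.
#' @param sig a `SignalSet` from [build_signal_sets()].
#' @param patient_id optional identifier carried into the result.
#' @return data frame row: `patient_id`, `r_par`, `r_met`, `s`.
#' @export
score_patient <- function(patient_signal, sig, patient_id = NA_character_) {
  if (!inherits(sig, "SignalSet")) stop("`sig` must be a SignalSet")
  if (length(patient_signal) != length(sig$peak_ids))
    stop("patient vector must align to the signature peaks")
  if (stats::sd(patient_signal) == 0)
    stop("patient signal is constant; correlation undefined")
  if (stats::sd(sig$par_signal) == 0 || stats::sd(sig$met_signal) == 0)
    stop("signal set is constant; correlation undefined")
  r_par <- stats::cor(patient_signal, sig$par_signal)
  r_met <- stats::cor(patient_signal, sig$met_signal)
  data.frame(patient_id = patient_id, r_par = r_par, r_met = r_met,
             s = r_met - r_par + 1, stringsAsFactors = FALSE)
}

#' metATAC scores for a cohort
#'
#' Applies [score_patient()] to every row of a patients-by-signature-peaks
#' matrix.  Per-patient failures (constant vectors) are reported as `NA`
#' rows with a warning; the remaining patients are scored.
#'
#' @param cohort_signal numeric matrix, patients in rows (rownames =
#'   patient ids), columns aligned to `sig$peak_ids`.
#' @param sig a `SignalSet`.
#' @return data frame: `patient_id`, `r_par`, `r_met`, `s`.
#' @export
score_cohort <- function(cohort_signal, sig) {
  cohort_signal <- as.matrix(cohort_signal)
  if (ncol(cohort_signal) != length(sig$peak_ids))
    stop("cohort columns must align to the signature peaks")
  ids <- rownames(cohort_signal)
  if (is.null(ids)) ids <- sprintf("patient_%d", seq_len(nrow(cohort_signal)))
  rows <- lapply(seq_len(nrow(cohort_signal)), function(i) {
    tryCatch(score_patient(cohort_signal[i, ], sig, patient_id = ids[i]),
             error = function(e) {
               warning(sprintf("patient %s not scored: %s", ids[i],
                               conditionMessage(e)), call. = FALSE)
               data.frame(patient_id = ids[i], r_par = NA_real_,
                          r_met = NA_real_, s = NA_real_,
                          stringsAsFactors = FALSE)
             })
  })
  do.call(rbind, rows)
}

#' Median stratification of scores
#'
#' Scores above the median are labelled `high`, all others (including
#' scores exactly at the median) `low`.
#'
#' @param scores numeric vector (length >= 2, not all equal).
#' @return factor with levels `low`, `high`, same order as `scores`.
#' @export
stratify_median <- function(scores) {
  if (length(scores) < 2L) stop("need >= 2 scores")
  if (any(is.na(scores))) stop("scores contain NA")
  if (length(unique(scores)) == 1L)
    stop("all scores identical; median split undefined")
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}
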