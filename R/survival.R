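#' Assemble a patient cohort table
#'
#' Bundles clinical annotations with a z-scored expression matrix.  The
#' clinical frame needs `patient_id`, `time` (months, > 0) and one or more
#' event indicator columns (`event`, or site-specific `event_lung`,
#' `event_brain`, `event_any`, each 0/1 — relapse at another site is
#' treated as censoring at that time).  Any further columns are available
#' as covariates.
#'
#' @param clinical data frame as described above.
#' @param expression optional numeric matrix, patients x genes, rownames
#'   matching `patient_id`.
#' @return list of class `CohortTable`: `clinical`, `expression`.
#' @export
cohort_table <- function(clinical, expression = NULL) {
  req <- c("patient_id", "time")
  if (!all(req %in% names(clinical)))
    stop("clinical needs columns: ", paste(req, collapse = ", "))
  if (any(clinical$time <= 0)) stop("time must be > 0")
  evcols <- grep("^event", names(clinical), value = TRUE)
  if (length(evcols) == 0L) stop("clinical needs at least one event column")
  for (ec in evcols)
    if (!all(clinical[[ec]] %in% c(0, 1)))
      stop(sprintf("%s must be 0/1", ec))
  if (anyDuplicated(clinical$patient_id)) stop("patient ids must be unique")
  if (!is.null(expression)) {
    expression <- as.matrix(expression)
    if (is.null(rownames(expression)) ||
        !setequal(rownames(expression), clinical$patient_id))
      stop("expression rownames must match patient_id")
    expression <- expression[clinical$patient_id, , drop = FALSE]
  }
  structure(list(clinical = clinical, expression = expression),
            class = "CohortTable")
}

#' Z-score expression per dataset, then merge
#'
#' To remove batch scale differences before pooling cohorts, each gene is
#' standardized (mean 0, sd 1, `n - 1` convention) within each dataset;
#' patients are then concatenated.  Genes constant within a dataset are
#' set to `NA` there with a warning.
#'
#' @param datasets named list of numeric matrices (patients x genes, all
#'   with the same gene columns).
#' @return list: `expression` (merged matrix), `dataset_id` (per patient).
#' @export
zscore_merge <- function(datasets) {
  if (is.null(names(datasets))) names(datasets) <- sprintf(
    "dataset_%d", seq_along(datasets))
  genes <- colnames(datasets[[1]])
  scaled <- lapply(names(datasets), function(nm) {
    m <- as.matrix(datasets[[nm]])
    if (!identical(colnames(m), genes))
      stop("all datasets must share the same gene columns")
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0, na.rm = TRUE))
      warning(sprintf("dataset %s: constant gene(s) set to NA: %s", nm,
                      paste(genes[which(sds == 0)], collapse = ", ")),
              call. = FALSE)
    z <- scale(m)
    z[, which(sds == 0)] <- NA_real_
    z
  })
  merged <- do.call(rbind, scaled)
  list(expression = merged,
       dataset_id = rep(names(datasets),
                        vapply(datasets, nrow, integer(1))))
}

#' Median split on one gene's expression
#'
#' Same tie rule as [stratify_median()]: values above the median are
#' `high`, values at or below it `low`.
#'
#' @param cohort a [cohort_table()] with expression.
#' @param gene gene (column) name.
#' @return factor (`low`/`high`) per patient, in cohort order.
#' @export
median_split_gene <- function(cohort, gene) {
  if (!inherits(cohort, "CohortTable")) stop("`cohort` must be a CohortTable")
  if (is.null(cohort$expression) || !(gene %in% colnames(cohort$expression)))
    stop(sprintf("gene %s absent from the expression matrix", gene))
  stratify_median(cohort$expression[, gene])
}

#' Two-group log-rank test
#'
#' @param groups two-level factor or character vector.
#' @param time time-to-event.
#' @param event 0/1 event indicator (>= 1 event required).
#' @return list: `chi2`, `p` (1 df chi-square).
#' @export
logrank <- function(groups, time, event) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("exactly two groups required")
  if (sum(event) < 1) stop("at least one event required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Covariate-adjusted Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling.  Categorical covariates
#' are encoded with the most frequent category as reference.  Reports the
#' exposure hazard ratio with Wald p-value and 95% confidence interval.
#'
#' @param cohort a [cohort_table()].
#' @param exposure per-patient exposure: two-level factor/character (e.g.
#'   from [median_split_gene()]) or numeric.
#' @param covariates character vector of clinical column names to adjust
#'   for (default none).
#' @param event_col which event indicator column to use (default
#'   `"event"`).
#' @return list of class `SurvivalResult`: `hr`, `ci` (length 2), `p`,
#'   `coef`, `se`, `n`, `n_events`.
#' @export
cox_ph <- function(cohort, exposure, covariates = character(0),
                   event_col = "event") {
  if (!inherits(cohort, "CohortTable")) stop("`cohort` must be a CohortTable")
  cl <- cohort$clinical
  if (!event_col %in% names(cl)) stop("missing event column: ", event_col)
  if (length(exposure) != nrow(cl))
    stop("exposure must have one value per patient")
  dat <- data.frame(.time = cl$time, .event = cl[[event_col]])
  if (is.numeric(exposure)) {
    dat$.exposure <- exposure
    expo_term <- ".exposure"
  } else {
    f <- factor(exposure)
    if (nlevels(droplevels(f)) != 2L)
      stop("categorical exposure must have exactly two levels")
    dat$.exposure <- f
    expo_term <- paste0(".exposure", levels(f)[2])
  }
  for (cv in covariates) {
    if (!cv %in% names(cl)) stop("missing covariate: ", cv)
    v <- cl[[cv]]
    if (length(unique(v)) == 1L)
      stop(sprintf("covariate %s is constant", cv))
    if (!is.numeric(v)) {
      tab <- sort(table(v), decreasing = TRUE)
      v <- stats::relevel(factor(v), ref = names(tab)[1])
    }
    dat[[cv]] <- v
  }
  n_coef <- 1L + sum(vapply(covariates, function(cv) {
    v <- dat[[cv]]
    if (is.factor(v)) nlevels(v) - 1L else 1L
  }, integer(1)))
  if (sum(dat$.event) < n_coef)
    stop(sprintf("only %d events for %d coefficients; reduce the model",
                 sum(dat$.event), n_coef))
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~ .exposure",
    if (length(covariates) > 0) paste("+", paste(covariates, collapse = " + "))
    else ""))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop("Cox fit failed (possible complete separation): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  if (!expo_term %in% rownames(co))
    stop("exposure coefficient not found in the fit")
  beta <- co[expo_term, "coef"]
  se <- co[expo_term, "se(coef)"]
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15)
    stop("Cox fit diverged for the exposure (complete separation?)")
  structure(list(hr = exp(beta),
                 ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p = co[expo_term, "Pr(>|z|)"],
                 coef = beta, se = se, n = nrow(dat),
                 n_events = sum(dat$.event),
                 score_chi2 = unname(sm$sctest["test"])),
            class = "SurvivalResult")
}

#' Per-TF relapse screen
#'
#' For each transcription factor: median-split the cohort on its
#' expression, run the log-rank test and a covariate-adjusted Cox fit for
#' relapse at the requested site, and BH-adjust p-values across the
#' screened TFs.  When the motif direction of each TF (`gained`/`lost`) is
#' supplied, a concordance flag joins the hazard direction with the motif
#' direction (gained with HR > 1, lost with HR < 1).
#'
#' @param cohort a [cohort_table()] with expression.
#' @param tf_list character vector of gene columns to screen.
#' @param site `"lung"`, `"brain"` or `"any"`; selects the event column
#'   `event_<site>` (falling back to `event`).
#' @param covariates clinical columns passed to [cox_ph()].
#' @param motif_direction optional named vector, TF -> `gained`/`lost`.
#' @return data frame: `tf`, `logrank_chi2`, `logrank_p`, `logrank_padj`,
#'   `cox_hr`, `cox_lo`, `cox_hi`, `cox_p`, `cox_padj`, `concordant`,
#'   `error` (message for per-TF failures, `NA` otherwise).
#' @export
tf_relapse_screen <- function(cohort, tf_list, site = c("any", "lung", "brain"),
                              covariates = character(0),
                              motif_direction = NULL) {
  site <- match.arg(site)
  ec <- paste0("event_", site)
  if (!ec %in% names(cohort$clinical)) ec <- "event"
  rows <- lapply(tf_list, function(tf) {
    out <- data.frame(tf = tf, logrank_chi2 = NA_real_, logrank_p = NA_real_,
                      cox_hr = NA_real_, cox_lo = NA_real_, cox_hi = NA_real_,
                      cox_p = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    tryCatch({
      grp <- median_split_gene(cohort, tf)
      lr <- logrank(grp, cohort$clinical$time, cohort$clinical[[ec]])
      cx <- cox_ph(cohort, grp, covariates = covariates, event_col = ec)
      out$logrank_chi2 <- lr$chi2; out$logrank_p <- lr$p
      out$cox_hr <- cx$hr; out$cox_lo <- cx$ci[1]; out$cox_hi <- cx$ci[2]
      out$cox_p <- cx$p
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(tf = character(0), logrank_chi2 = numeric(0),
                      logrank_p = numeric(0), cox_hr = numeric(0),
                      cox_lo = numeric(0), cox_hi = numeric(0),
                      cox_p = numeric(0), error = character(0),
                      stringsAsFactors = FALSE)
  }
  ok <- !is.na(res$logrank_p)
  res$logrank_padj <- rep(NA_real_, nrow(res))
  res$logrank_padj[ok] <- bh_adjust(res$logrank_p[ok])
  res$cox_padj <- rep(NA_real_, nrow(res))
  okc <- !is.na(res$cox_p)
  res$cox_padj[okc] <- bh_adjust(res$cox_p[okc])
  res$concordant <- rep(NA, nrow(res))
  if (!is.null(motif_direction)) {
    dirs <- motif_direction[res$tf]
    res$concordant <- ifelse(is.na(res$cox_hr) | is.na(dirs), NA,
                             (dirs == "gained" & res$cox_hr > 1) |
                             (dirs == "lost" & res$cox_hr < 1))
  }
  res
}
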