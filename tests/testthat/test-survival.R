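toy_cohort <- function(time, event, expr = NULL, extra = NULL) {
  n <- length(time)
  cl <- data.frame(patient_id = sprintf("pt%03d", seq_len(n)),
                   time = time, event = event, stringsAsFactors = FALSE)
  if (!is.null(extra)) cl <- cbind(cl, extra)
  if (!is.null(expr)) rownames(expr) <- cl$patient_id
  cohort_table(cl, expr)
}

test_that("z-score merging standardizes each dataset and is idempotent", {
  d1 <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "gene1"))
  z <- zscore_merge(list(A = d1))
  expect_equal(unname(z$expression[, 1]), c(-sqrt(2) / 2, sqrt(2) / 2),
               tolerance = 1e-10)
  set.seed(61)
  d2 <- matrix(rnorm(40, 10, 3), 20, 2,
               dimnames = list(NULL, c("g1", "g2")))
  d3 <- matrix(rnorm(30, -5, 0.2), 15, 2,
               dimnames = list(NULL, c("g1", "g2")))
  m <- zscore_merge(list(A = d2, B = d3))
  for (ds in c("A", "B")) for (g in c("g1", "g2")) {
    v <- m$expression[m$dataset_id == ds, g]
    expect_equal(mean(v), 0, tolerance = 1e-6)
    expect_equal(sd(v), 1, tolerance = 1e-6)
  }
  # already standardized data passes through unchanged
  again <- zscore_merge(list(A = m$expression[m$dataset_id == "A", ]))
  expect_equal(unname(again$expression),
               unname(m$expression[m$dataset_id == "A", ]),
               tolerance = 1e-10)
  # constant gene -> NA with warning
  d4 <- matrix(c(1, 1, 1, 2, 3, 4), 3, 2,
               dimnames = list(NULL, c("g1", "g2")))
  expect_warning(zc <- zscore_merge(list(A = d4)), "constant")
  expect_true(all(is.na(zc$expression[, "g1"])))
})

test_that("log-rank matches the textbook O-E/V computation", {
  grp <- factor(rep(c("A", "B"), each = 3))
  time <- c(1, 2, 3, 4, 5, 6); event <- rep(1, 6)
  lr <- logrank(grp, time, event)
  expect_equal(lr$chi2, logrank_oracle(grp, time, event), tolerance = 1e-8)
  # identical event patterns -> chi2 = 0, p = 1
  same <- logrank(factor(rep(c("A", "B"), 3)), rep(c(1, 2, 3), each = 2),
                  rep(1, 6))
  expect_equal(same$chi2, 0, tolerance = 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-10)
  # label swap leaves the statistic unchanged
  swapped <- logrank(factor(rep(c("B", "A"), each = 3)), time, event)
  expect_equal(swapped$chi2, lr$chi2)
  expect_error(logrank(factor(rep("A", 6)), time, event), "two groups")
  set.seed(62)
  for (i in 1:5) {
    t2 <- rexp(30, 0.1); e2 <- rbinom(30, 1, 0.7)
    g2 <- factor(sample(c("A", "B"), 30, TRUE))
    expect_equal(logrank(g2, t2, e2)$chi2, logrank_oracle(g2, t2, e2),
                 tolerance = 1e-8)
  }
})

test_that("log-rank p agrees with a permutation null on a toy cohort", {
  set.seed(63)
  n <- 24
  time <- round(rexp(n, 0.1), 3); event <- rbinom(n, 1, 0.8)
  grp <- factor(rep(c("A", "B"), each = n / 2))
  obs <- logrank(grp, time, event)
  B <- 4000
  perm <- vapply(seq_len(B), function(b)
    logrank_oracle(sample(grp), time, event), numeric(1))
  p_perm <- mean(perm >= obs$chi2)
  expect_lt(abs(obs$p - p_perm), 0.05)
})

test_that("Cox score test at the null equals the log-rank statistic", {
  set.seed(64)
  n <- 40
  time <- rexp(n, 0.05) + runif(n, 0, 1e-4)  # no ties
  event <- rbinom(n, 1, 0.8)
  grp <- factor(sample(c("low", "high"), n, TRUE), levels = c("low", "high"))
  co <- toy_cohort(time, event)
  fit <- cox_ph(co, grp)
  lr <- logrank(grp, time, event)
  expect_equal(fit$score_chi2, lr$chi2, tolerance = 1e-6)
})

test_that("Cox HR is invariant to duplicating every patient", {
  set.seed(65)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.02 * exp(0.6 * x)); event <- rep(1, n)
  co1 <- toy_cohort(time, event)
  grp <- factor(ifelse(x == 1, "high", "low"), levels = c("low", "high"))
  f1 <- cox_ph(co1, grp)
  co2 <- toy_cohort(rep(time, 2), rep(event, 2))
  f2 <- cox_ph(co2, rep(grp, 2))
  # duplication creates ties, so Efron's correction perturbs the
  # partial likelihood slightly; the point estimate stays put to ~1%
  expect_equal(f2$hr, f1$hr, tolerance = 0.02)
  expect_true(f1$ci[1] <= f1$hr && f1$hr <= f1$ci[2])
})

test_that("Cox fit validates covariates and event counts", {
  set.seed(66)
  n <- 30
  extra <- data.frame(age = rnorm(n, 60, 10), flat = rep(1, n))
  co <- toy_cohort(rexp(n, 0.05), rbinom(n, 1, 0.5), extra = extra)
  grp <- factor(rep(c("low", "high"), n / 2), levels = c("low", "high"))
  expect_error(cox_ph(co, grp, covariates = "flat"), "constant")
  expect_error(cox_ph(co, grp, covariates = "nope"), "missing covariate")
  few <- toy_cohort(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_error(cox_ph(few, factor(c("low", "high", "low", "high"),
                                  levels = c("low", "high"))),
               "events")
  # adjusted fit runs and reports a finite CI
  fit <- cox_ph(co, grp, covariates = "age")
  expect_true(is.finite(fit$hr) && fit$ci[1] > 0)
})

test_that("the TF relapse screen flags planted hazards as concordant", {
  set.seed(67)
  n <- 300
  w <- runif(n)
  expr <- cbind(TF_GAIN = 2 * w + rnorm(n, 0, 0.3),
                TF_NULL = rnorm(n))
  t_ev <- rexp(n, 0.02 * exp(1.2 * w)); t_c <- runif(n, 20, 100)
  extra <- data.frame(age = rnorm(n, 58, 10), er = rbinom(n, 1, 0.6))
  co <- toy_cohort(pmin(t_ev, t_c), as.integer(t_ev <= t_c), expr = expr,
                   extra = extra)
  scr <- tf_relapse_screen(co, c("TF_GAIN", "TF_NULL"), site = "any",
                           covariates = c("age", "er"),
                           motif_direction = c(TF_GAIN = "gained",
                                               TF_NULL = "lost"))
  g <- scr[scr$tf == "TF_GAIN", ]
  expect_gt(g$cox_hr, 1)
  expect_true(g$concordant)
  expect_lt(g$logrank_p, 0.05)
  # per-TF failure is reported, screen continues
  scr2 <- tf_relapse_screen(co, c("TF_GAIN", "absent"), site = "any")
  expect_false(is.na(scr2$error[scr2$tf == "absent"]))
  expect_false(is.na(scr2$cox_hr[scr2$tf == "TF_GAIN"]))
  expect_equal(nrow(tf_relapse_screen(co, character(0))), 0)
})
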