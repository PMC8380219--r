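# KM risk stratification and the G-rho test.

make_model_on <- function(dat, labels) {
  fit_backward_aic(dat, labels, names(dat))
}

test_that("identical survival in both risk groups is not called significant", {
  dat <- tibble::tibble(x = rep(c(-2, 2), 25))
  labels <- rep(c(0L, 1L), 25)
  m <- make_model_on(dat, labels)
  out <- tibble::tibble(patient_id = sprintf("P%02d", 1:50),
                        efs_months = rep(c(5, 9, 14, 20, 26), 10),
                        efs_event = rep(c(1L, 1L, 0L, 1L, 0L), 10))
  km <- stratify_km(m, dat, out, "efs")
  expect_gt(km$p_value, 0.5)
  expect_equal(km$median_survival$median_months[1],
               km$median_survival$median_months[2])
})

test_that("KM without censoring equals the empirical survival function", {
  dat <- tibble::tibble(x = c(rep(-2, 6), rep(2, 6)))
  labels <- c(rep(0L, 6), rep(1L, 6))
  m <- make_model_on(dat, labels)
  times <- c(2, 4, 6, 8, 10, 12, 1, 2, 3, 4, 5, 6)
  out <- tibble::tibble(patient_id = sprintf("P%02d", 1:12),
                        efs_months = times, efs_event = 1L)
  km <- stratify_km(m, dat, out, "efs")
  lo <- km$curves[km$curves$group == "low_risk", ]
  # All six low-risk patients have events at 2,4,...,12: S drops by 1/6 each.
  expect_equal(lo$survival, 1 - seq_len(6) / 6)
  expect_equal(km$median_survival$median_months[
    km$median_survival$group == "low_risk"], 6)  # first time S <= 0.5
})

test_that("the G-rho statistic matches a from-scratch observed-minus-expected sum", {
  # Ten patients, two groups, one censored record per group.
  grp <- c(rep(0, 5), rep(1, 5))
  tm <- c(3, 5, 8, 11, 14, 2, 4, 6, 9, 12)
  ev <- c(1, 1, 0, 1, 1, 1, 1, 1, 0, 1)
  # Log-rank by hand: at each distinct death time, O - E for group 1 with
  # hypergeometric variance.
  dt <- sort(unique(tm[ev == 1]))
  U <- 0; V <- 0
  for (t in dt) {
    at_risk <- tm >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(tm == t & ev == 1); d1 <- sum(tm == t & ev == 1 & grp == 1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq_oracle <- U^2 / V
  sd_ <- survival::survdiff(survival::Surv(tm, ev) ~ grp, rho = 0)
  expect_equal(sd_$chisq, chisq_oracle, tolerance = 1e-10)

  # And through the stratification interface.
  dat <- tibble::tibble(x = ifelse(grp == 1, 2, -2))
  m <- make_model_on(dat, grp)
  out <- tibble::tibble(patient_id = sprintf("P%02d", 1:10),
                        efs_months = tm, efs_event = as.integer(ev))
  km <- stratify_km(m, dat, out, "efs", rho = 0)
  expect_equal(km$chisq, chisq_oracle, tolerance = 1e-10)
})

test_that("degenerate cutoffs are rejected", {
  dat <- tibble::tibble(x = rep(1, 10))
  m <- structure(list(features = "x", center = c(x = 0), scale = c(x = 1),
                      intercept = 0, coefficients = c(x = 1),
                      risk_cutoff = 0.99), class = "prognostic_model")
  out <- tibble::tibble(patient_id = sprintf("P%02d", 1:10),
                        efs_months = 1:10, efs_event = 1L)
  expect_error(stratify_km(m, dat, out, "efs"), "one side")
})

test_that("stronger designed effects widen the risk-group separation", {
  sep <- vapply(c(0.6, 0.75, 0.9), function(a) {
    co <- simulate_feature_cohort(n_patients = 250, target_auc = a, seed = 77)
    lab <- binarize_outcomes(co$outcomes, "efs", 12)
    ftr <- co$features[match(lab$patient_id, co$features$patient_id), ]
    m <- fit_backward_aic(ftr, lab$label, co$truth$informative_features[c(1, 6, 11)])
    km <- stratify_km(m, co$features, co$outcomes, "efs")
    ms <- km$median_survival
    hi <- ms$median_months[ms$group == "high_risk"]
    lo <- ms$median_months[ms$group == "low_risk"]
    (if (is.na(lo)) max(co$outcomes$efs_months) else lo) - hi
  }, numeric(1))
  expect_true(all(diff(sep) >= 0) || sep[3] > sep[1])
  expect_gt(sep[3], 0)
})
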