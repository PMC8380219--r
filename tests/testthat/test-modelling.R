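test_that("binarization assigns event, non-event and excluded correctly", {
  out <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                        efs_months = c(10, 8, 30, 12),
                        efs_event = c(1L, 0L, 0L, 1L))
  b12 <- binarize_outcomes(out, "efs", 12)
  expect_equal(b12$label[b12$patient_id == "a"], 1L)   # event at 10
  expect_false("b" %in% b12$patient_id)                # censored at 8
  expect_equal(b12$label[b12$patient_id == "c"], 0L)   # follow-up past horizon
  expect_equal(b12$label[b12$patient_id == "d"], 1L)   # event exactly at horizon
  expect_equal(attr(b12, "n_excluded"), 1L)
  b24 <- binarize_outcomes(out, "efs", 24)
  expect_equal(b24$label[b24$patient_id == "c"], 0L)   # censored at 30 > 24
  # Censored-as-nonevent policy keeps everyone.
  b12n <- binarize_outcomes(out, "efs", 12, censored = "nonevent")
  expect_equal(nrow(b12n), 4)
  out$efs_months[1] <- -1
  expect_error(binarize_outcomes(out, "efs", 12), "negative")
})

test_that("Horn parallel analysis separates planted factors from noise", {
  # Pure noise: at most one component retained in the vast majority of seeds.
  retained <- vapply(1:10, function(s) {
    X <- withr::with_seed(s, matrix(rnorm(100 * 20), 100, 20))
    horn_components(X, n_reps = 100, seed = s + 500)
  }, integer(1))
  expect_gte(mean(retained <= 1), 0.9)

  # Three planted orthogonal factors, 14 features each (loadings 1/0.85/0.7,
  # measurement noise sd 0.3), remaining 8 features independent noise.
  X <- withr::with_seed(1, {
    f <- matrix(rnorm(200 * 3), 200, 3)
    X <- matrix(rnorm(200 * 50), 200, 50)
    for (k in 1:3) {
      X[, (k - 1) * 14 + 1:14] <- c(1, 0.85, 0.7)[k] * f[, k] +
        0.3 * matrix(rnorm(200 * 14), 200, 14)
    }
    X
  })
  expect_equal(horn_components(X, n_reps = 200, seed = 3), 3L)
  expect_error(horn_components(X, n_reps = 0), "positive")
  expect_error(horn_components(X[, 1, drop = FALSE]), ">= 2")
})

test_that("PCA grouping recovers planted correlation blocks", {
  X <- withr::with_seed(2, {
    f <- matrix(rnorm(150 * 2), 150, 2)
    cbind(f[, 1] + 0.15 * rnorm(150), f[, 1] + 0.15 * rnorm(150),
          f[, 1] + 0.15 * rnorm(150), f[, 2] + 0.6 * rnorm(150),
          f[, 2] + 0.6 * rnorm(150), f[, 2] + 0.6 * rnorm(150))
  })
  colnames(X) <- paste0("f", 1:6)
  g <- group_features(X, 2)
  expect_length(unique(g$group[1:3]), 1)
  expect_length(unique(g$group[4:6]), 1)
  expect_true(g$group[1] != g$group[4])

  # Perfectly correlated pair lands in the same group.
  Y <- cbind(a = X[, 1], b = 2 * X[, 1] + 3, c = X[, 4])
  g2 <- group_features(Y, 2)
  expect_equal(g2$group[1], g2$group[2])

  # One component: everything in one group; constants go to the sentinel.
  g3 <- group_features(X, 1)
  expect_length(unique(g3$group), 1)
  Z <- cbind(X, const = rep(1, 150))
  expect_warning(g4 <- group_features(Z, 2), "zero-variance")
  expect_equal(g4$group[g4$feature == "const"], 0L)
})

test_that("Mann-Whitney AUC equals exhaustive pairwise concordance", {
  # Printed 6-point toy set: cases {3, 5, 5}, controls {1, 2, 5}.
  x <- c(3, 5, 5, 1, 2, 5)
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auc_mw(x, y), oracle_auc(x, y))
  # Concordant pairs: case 3 beats {1,2}; each case 5 beats {1,2} and ties 5.
  expect_equal(auc_mw(x, y), (2 + 2.5 + 2.5) / 9)

  for (s in 1:20) {
    n <- withr::with_seed(s, sample(6:30, 1))
    xs <- withr::with_seed(s + 40, round(rnorm(n), 1))  # ties likely
    ys <- withr::with_seed(s + 80, rbinom(n, 1, 0.5))
    if (length(unique(ys)) < 2) next
    expect_equal(auc_mw(xs, ys), oracle_auc(xs, ys), tolerance = 1e-12)
  }

  expect_equal(auc_mw(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)  # separation
  expect_error(auc_mw(1:4, rep(1, 4)), "both classes")
})

test_that("univariable screening keeps informative surrogates, drops null ones", {
  dat <- withr::with_seed(9, {
    n <- 200
    f <- rnorm(n)
    tibble::tibble(good1 = f + 0.3 * rnorm(n), good2 = f + 0.3 * rnorm(n),
                   null1 = rnorm(n), null2 = rnorm(n))
  })
  labels <- withr::with_seed(10, rbinom(200, 1, plogis(1.5 * scale(dat$good1 + dat$good2))))
  groups <- tibble::tibble(feature = names(dat), group = c(1L, 1L, 2L, 2L))
  sc <- univariable_screen(dat, labels, groups)
  expect_equal(nrow(sc), 2)
  g1 <- sc[sc$group == 1, ]
  expect_true(g1$candidate)
  expect_gt(g1$auc, 0.65)
  g2 <- sc[sc$group == 2, ]
  expect_lt(g2$auc, 0.62)
  expect_error(univariable_screen(dat, rep(1, 200), groups), "single class")
})

test_that("backward AIC drops planted noise and matches the AIC definition", {
  # Across seeds, the signal survives always and pure noise almost always
  # falls out (AIC keeps a null variable only when |z| > ~1.4 by chance).
  kept_noise <- 0
  for (s in 1:6) {
    dat <- withr::with_seed(s, tibble::tibble(signal = rnorm(200),
                                              noise = rnorm(200)))
    labels <- withr::with_seed(s + 50, rbinom(200, 1, plogis(1.2 * dat$signal)))
    m <- fit_backward_aic(dat, labels, c("signal", "noise"))
    expect_true("signal" %in% m$features)
    kept_noise <- kept_noise + ("noise" %in% m$features)
  }
  expect_lte(kept_noise, 1)

  dat <- withr::with_seed(4, tibble::tibble(signal = rnorm(200),
                                            noise = rnorm(200)))
  labels <- withr::with_seed(54, rbinom(200, 1, plogis(1.2 * dat$signal)))
  m <- fit_backward_aic(dat, labels, c("signal", "noise"))
  # AIC = 2k - 2 logLik recomputed from the reported fit.
  probs <- predict(m, dat)
  ll <- sum(labels * log(probs) + (1 - labels) * log(1 - probs))
  expect_equal(m$aic, 2 * m$n_parameters - 2 * ll, tolerance = 1e-6)
  expect_equal(m$log_likelihood, ll, tolerance = 1e-6)

  null <- fit_backward_aic(dat, labels, character(0))
  expect_length(null$features, 0)
  expect_equal(null$training_auc, 0.5)
  expect_true(all(predict(null, dat) == predict(null, dat)[1]))
})

test_that("backward AIC never increases AIC relative to the start model", {
  for (s in 1:5) {
    dat <- withr::with_seed(s, tibble::as_tibble(
      matrix(rnorm(150 * 6), 150, 6, dimnames = list(NULL, paste0("v", 1:6)))))
    labels <- withr::with_seed(s + 9, rbinom(150, 1, plogis(0.8 * dat$v1)))
    start <- suppressWarnings(stats::glm(labels ~ ., family = binomial(),
                                         data = cbind(dat, labels = labels)))
    m <- fit_backward_aic(dat, labels, names(dat))
    expect_lte(m$aic, stats::AIC(start) + 1e-8)
  }
})

test_that("separation is flagged and handled by the penalized fallback", {
  dat <- withr::with_seed(71, tibble::tibble(x = c(rnorm(20, -3), rnorm(20, 3))))
  labels <- rep(c(0L, 1L), each = 20)
  m <- fit_backward_aic(dat, labels, "x")
  expect_true(m$separation)
  expect_match(m$notes, "ridge")
  expect_true(all(is.finite(predict(m, dat))))
})

test_that("cross-validation is deterministic and honest under the null", {
  co <- simulate_feature_cohort(n_patients = 150, seed = 31)
  lab <- binarize_outcomes(co$outcomes, "efs", 12)
  ftr <- co$features[match(lab$patient_id, co$features$patient_id), ]
  cv1 <- cross_validate(ftr, lab$label, k = 5, seed = 7, horn_reps = 50)
  cv2 <- cross_validate(ftr, lab$label, k = 5, seed = 7, horn_reps = 50)
  expect_identical(cv1, cv2)
  expect_equal(cv1$cv_auc_range, max(cv1$fold_auc) - min(cv1$fold_auc))

  perm <- withr::with_seed(8, sample(lab$label))
  cvp <- cross_validate(ftr, perm, k = 5, seed = 7, horn_reps = 50)
  expect_lt(abs(cvp$cv_auc_mean - 0.5), 0.10)

  expect_error(cross_validate(ftr[1:8, ], lab$label[1:8], k = 5), "smaller k")
})

test_that("model selection uses the documented mean-range trade-off", {
  models <- tibble::tibble(endpoint_id = c("a", "b"),
                           cv_auc_mean = c(0.80, 0.78),
                           cv_auc_range = c(0.10, 0.40))
  ranked <- select_best(models, lambda = 0.5)
  expect_equal(ranked$endpoint_id[1], "a")
  expect_equal(ranked$score, c(0.75, 0.58))
  # Ties break lexicographically by endpoint id.
  tie <- tibble::tibble(endpoint_id = c("z_ep", "a_ep"),
                        cv_auc_mean = c(0.7, 0.7), cv_auc_range = c(0.1, 0.1))
  expect_equal(select_best(tie)$endpoint_id[1], "a_ep")
  expect_equal(select_best(models[1, ])$endpoint_id, "a")
  expect_error(select_best(models[0, ]), "empty")
})

test_that("external validation: perfect separation on the training set", {
  dat <- withr::with_seed(72, tibble::tibble(x = c(rnorm(25, -4), rnorm(25, 4))))
  labels <- rep(c(0L, 1L), each = 25)
  m <- fit_backward_aic(dat, labels, "x")
  v <- suppressWarnings(validate_model(m, dat, labels))
  expect_equal(v$auc, 1)
  expect_equal(v$ci95[2], 1)
  expect_error(validate_model(m, dat, rep(1L, 50)), "one class")
})

test_that("prognostic overlap matches direct set arithmetic", {
  tr <- withr::with_seed(61, tibble::tibble(
    f1 = c(rnorm(30, 0), rnorm(30, 2)),
    f2 = rnorm(60), f3 = c(rnorm(30, 0), rnorm(30, 1.5))))
  va <- withr::with_seed(62, tibble::tibble(
    f1 = c(rnorm(20, 0), rnorm(20, 2)),
    f2 = rnorm(40), f3 = c(rnorm(20, 0), rnorm(20, 1.5))))
  ltr <- rep(c(0, 1), each = 30); lva <- rep(c(0, 1), each = 20)
  stab <- tibble::tibble(feature = c("f1", "f2", "f3"),
                         delineation = c(TRUE, TRUE, FALSE),
                         attenuation = c(FALSE, TRUE, FALSE),
                         motion = c(TRUE, TRUE, TRUE))
  ov <- prognostic_overlap(tr, ltr, va, lva, stab)
  manual <- intersect(
    names(tr)[vapply(names(tr), function(f) auc_mw(tr[[f]], ltr, TRUE) > 0.6, TRUE)],
    names(va)[vapply(names(va), function(f) auc_mw(va[[f]], lva, TRUE) > 0.6, TRUE)])
  expect_setequal(ov$prognostic_features, manual)
  st <- stab[match(ov$prognostic_features, stab$feature), ]
  expect_equal(unname(ov$pct_stable["delineation"]), 100 * mean(st$delineation))
  expect_equal(unname(ov$pct_stable["motion"]), 100 * mean(st$motion))

  # All-stable and empty-set edge cases.
  stab_all <- dplyr::mutate(stab, delineation = TRUE, attenuation = TRUE)
  ov_all <- prognostic_overlap(tr, ltr, va, lva, stab_all)
  expect_true(all(ov_all$pct_stable == 100))
  ov_empty <- prognostic_overlap(tr["f2"], ltr, va["f2"], lva, stab)
  expect_true(ov_empty$empty)
  expect_true(all(is.na(ov_empty$pct_stable)))
})
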