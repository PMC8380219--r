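#' Outcome-linked synthetic cohorts
#'
#' Cohorts tie binary survival outcomes to image features through a logistic
#' model: the probability of an event before the horizon is
#' `plogis(intercept + sum(coef * z))` with `z` the standardized feature
#' values. Event times are exponential with the rate calibrated per patient
#' so that `P(T <= horizon)` equals that probability; censoring is applied
#' independently. Overall survival is modelled as event-free survival plus an
#' exponential post-event survival tail.
#'
#' @param n_patients cohort size.
#' @param seed master seed.
#' @param outcome_feature_names features carrying the signal.
#' @param outcome_coefficients log-odds per standardized feature unit.
#' @param intercept logistic intercept.
#' @param censoring_rate fraction of patients with independent censoring.
#' @param horizon_months design horizon for the binarized endpoint.
#' @return `cohort_spec()`: a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, seed = 1L, outcome_feature_names,
                        outcome_coefficients, intercept = 0,
                        censoring_rate = 0.15, horizon_months = 12) {
  stopifnot(n_patients > 0, horizon_months > 0,
            censoring_rate >= 0, censoring_rate <= 1,
            length(outcome_feature_names) == length(outcome_coefficients))
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         outcome_feature_names = outcome_feature_names,
         outcome_coefficients = as.numeric(outcome_coefficients),
         intercept = intercept, censoring_rate = censoring_rate,
         horizon_months = horizon_months),
    class = "cohort_spec"
  )
}

# Survival times from per-patient event probabilities at the horizon.
draw_outcomes <- function(eta, cspec, seed) {
  p <- stats::plogis(eta)
  n <- length(p)
  with_seed(seed, {
    rate_efs <- -log(pmax(1 - p, 1e-12)) / cspec$horizon_months
    t_efs <- stats::rexp(n, rate = pmax(rate_efs, 1e-12))
    t_os <- t_efs + stats::rexp(n, rate = 1 / 9)  # median ~6 months post-event tail
    censored <- stats::runif(n) < cspec$censoring_rate
    c_time <- stats::runif(n, 0, 2 * cspec$horizon_months)
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      efs_months = ifelse(censored & c_time < t_efs, c_time, t_efs),
      efs_event = as.integer(!(censored & c_time < t_efs)),
      os_months = ifelse(censored & c_time < t_os, c_time, t_os),
      os_event = as.integer(!(censored & c_time < t_os))
    )
  })
}

# Design AUC: probability that a (probability-weighted) case's linear
# predictor exceeds a control's, from the realized predictors.
design_auc_from_eta <- function(eta) {
  p <- stats::plogis(eta)
  w <- outer(p, 1 - p)              # weight of (case i, control j)
  gt <- outer(eta, eta, `>`) + 0.5 * outer(eta, eta, `==`)
  sum(w * gt) / sum(w)
}

#' Calibrate the logistic effect scale for a target design AUC
#'
#' For a linear predictor `eta ~ N(0, s^2)` and `P(case | eta) =
#' plogis(eta)`, returns the scale `s` whose population design AUC (the
#' probability a case's predictor exceeds a control's) equals `target_auc`.
#' Evaluated by Gauss–Hermite quadrature; deterministic.
#'
#' @param target_auc desired design AUC in (0.5, 0.99).
#' @return Scale `s` of the linear predictor.
#' @export
calibrate_effect_scale <- function(target_auc = 0.75) {
  stopifnot(target_auc > 0.5, target_auc < 0.99)
  gh <- gauss_hermite(80)
  pop_auc <- function(s) {
    eta <- sqrt(2) * s * gh$nodes
    w <- gh$weights / sqrt(pi)
    p <- stats::plogis(eta)
    wc <- w * p         # case weight
    wn <- w * (1 - p)   # control weight
    gt <- outer(eta, eta, `>`) + 0.5 * outer(eta, eta, `==`)
    sum(outer(wc, wn) * gt) / (sum(wc) * sum(wn))
  }
  stats::uniroot(function(s) pop_auc(s) - target_auc, c(1e-4, 20),
                 tol = 1e-8)$root
}

gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Simulate a feature-level cohort with known prognostic structure
#'
#' Tabular counterpart of the image-based cohort generator, used for
#' modelling studies at larger n: `n_factors` latent factors each load
#' `block_size` correlated features; the linear predictor is the scaled
#' factor sum (so its design AUC is known); the remaining features are
#' independent noise.
#'
#' @param n_patients cohort size.
#' @param n_features total number of features.
#' @param block_sizes informative features per latent factor (one entry per
#'   factor). Distinct block sizes keep the factor eigenvalues well
#'   separated, so principal components align with the blocks -- as they do
#'   for real correlation clusters of unequal size.
#' @param target_auc design AUC of the linear predictor.
#' @param feature_noise_sd measurement noise added to factor features.
#' @param loadings per-factor feature loadings.
#' @param censoring_rate,horizon_months passed to the outcome model.
#' @param seed master seed.
#' @return List with `features` (tibble, `patient_id` + feature columns),
#'   `outcomes` (EFS/OS table), and `truth` (linear predictors, realized
#'   design AUC, informative feature names).
#' @export
simulate_feature_cohort <- function(n_patients = 300, n_features = 25,
                                    block_sizes = c(7, 5, 3),
                                    target_auc = 0.75, feature_noise_sd = 0.3,
                                    loadings = seq(1, 0.7,
                                                   length.out = length(block_sizes)),
                                    censoring_rate = 0.1, horizon_months = 12,
                                    seed = 1L) {
  n_factors <- length(block_sizes)
  stopifnot(sum(block_sizes) <= n_features,
            length(loadings) == n_factors)
  s <- calibrate_effect_scale(target_auc)
  ends <- cumsum(block_sizes)
  sim <- with_seed(seed, {
    f <- matrix(stats::rnorm(n_patients * n_factors), n_patients, n_factors)
    eta <- s * rowSums(f) / sqrt(n_factors)
    X <- matrix(stats::rnorm(n_patients * n_features), n_patients, n_features)
    for (k in seq_len(n_factors)) {
      cols <- (ends[k] - block_sizes[k] + 1):ends[k]
      X[, cols] <- loadings[k] * f[, k] + feature_noise_sd *
        matrix(stats::rnorm(n_patients * block_sizes[k]), n_patients,
               block_sizes[k])
    }
    list(X = X, eta = eta)
  })
  informative <- sprintf("feat_%03d", seq_len(sum(block_sizes)))
  colnames(sim$X) <- sprintf("feat_%03d", seq_len(n_features))
  cspec <- cohort_spec(n_patients, seed = seed,
                       outcome_feature_names = informative,
                       outcome_coefficients = rep(s / sqrt(n_factors), length(informative)),
                       censoring_rate = censoring_rate,
                       horizon_months = horizon_months)
  outcomes <- draw_outcomes(sim$eta, cspec, derive_seed(seed, "outcomes"))
  features <- dplyr::bind_cols(tibble::tibble(patient_id = outcomes$patient_id),
                               tibble::as_tibble(sim$X))
  list(features = features, outcomes = outcomes,
       truth = list(eta = sim$eta,
                    design_auc = design_auc_from_eta(sim$eta),
                    informative_features = informative,
                    effect_scale = s))
}

#' Generate an image-based cohort of phantoms with linked outcomes
#'
#' Per patient, a randomized phantom is generated and its full feature
#' signature extracted; the event probability at the horizon follows the
#' logistic model on the standardized named features.
#'
#' @param cspec a [cohort_spec()]; `outcome_feature_names` must be names the
#'   extractor produces.
#' @param phantom_template a [phantom_spec()] randomization template.
#' @param config extraction parameters.
#' @return List with `cases` (phantom triplets), `features`, `outcomes`, and
#'   `truth` (per-patient linear predictors and realized design AUC).
#' @export
generate_cohort <- function(cspec, phantom_template = phantom_spec(),
                            config = extract_config()) {
  stopifnot(inherits(cspec, "cohort_spec"))
  cases <- vector("list", cspec$n_patients)
  for (p in seq_len(cspec$n_patients)) {
    pseed <- derive_seed(cspec$seed, paste0("cohort_patient_", p))
    ph <- generate_phantom(randomize_phantom_spec(phantom_template, pseed))
    cases[[p]] <- list(patient_id = sprintf("P%03d", p),
                       pet = ph$pet, ct = ph$ct, mask = ph$mask)
  }
  features <- extract_cohort_features(cases, config)
  bad <- setdiff(cspec$outcome_feature_names, names(features))
  if (length(bad) > 0) {
    stop_petrad("unknown outcome feature(s): ", paste(bad, collapse = ", "),
                ". Valid names are the extractor's feature names, e.g. ",
                paste(utils::head(setdiff(names(features), "patient_id"), 3),
                      collapse = ", "))
  }
  Z <- scale(as.matrix(features[, cspec$outcome_feature_names, drop = FALSE]))
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  eta <- cspec$intercept + as.numeric(Z %*% cspec$outcome_coefficients)
  outcomes <- draw_outcomes(eta, cspec, derive_seed(cspec$seed, "outcomes"))
  outcomes$patient_id <- features$patient_id
  list(cases = cases, features = features, outcomes = outcomes,
       truth = list(eta = eta, design_auc = design_auc_from_eta(eta)))
}
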