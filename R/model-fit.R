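#' Backward-AIC multivariable logistic model
#'
#' Starting from all candidate features (z-scored on the training data), the
#' variable whose removal most decreases the Akaike information criterion is
#' dropped, iterating until no removal decreases AIC; the retained model is
#' the maximum-likelihood logistic fit. If complete separation is detected
#' the coefficients are re-estimated with a weakly ridge-penalized IRLS and
#' the model is flagged.
#'
#' @param data feature tibble containing at least the candidate columns.
#' @param labels 0/1 outcome labels.
#' @param candidates character vector of candidate feature names (may be
#'   empty, giving the intercept-only null model).
#' @param endpoint optional endpoint description carried in the model.
#' @return A `prognostic_model`: selected features, training
#'   standardization, coefficients, AIC, risk cutoff (median training
#'   probability) and fit notes.
#' @export
fit_backward_aic <- function(data, labels, candidates,
                             endpoint = list(outcome = NA, horizon_months = NA,
                                             feature_set = NA)) {
  if (is.data.frame(data)) data <- data[, setdiff(names(data), "patient_id"), drop = FALSE]
  labels <- as.integer(labels)
  candidates <- intersect(candidates, names(data))

  centers <- vapply(candidates, function(f) mean(data[[f]]), numeric(1))
  scales <- vapply(candidates, function(f) stats::sd(data[[f]]), numeric(1))
  scales[scales == 0] <- 1
  Z <- if (length(candidates)) {
    sweep(sweep(as.matrix(data[candidates]), 2, centers), 2, scales, `/`)
  } else {
    matrix(numeric(0), nrow = length(labels), ncol = 0)
  }

  fit_set <- function(vars) {
    df <- data.frame(y = labels)
    if (length(vars)) df <- cbind(df, as.data.frame(Z[, vars, drop = FALSE]))
    suppressWarnings(stats::glm(y ~ ., family = stats::binomial(), data = df))
  }
  current <- candidates
  fit <- fit_set(current)
  repeat {
    if (length(current) == 0) break
    aics <- vapply(current, function(v) stats::AIC(fit_set(setdiff(current, v))),
                   numeric(1))
    if (min(aics) < stats::AIC(fit) - 1e-8) {
      current <- setdiff(current, current[which.min(aics)])
      fit <- fit_set(current)
    } else break
  }

  probs <- as.numeric(stats::fitted(fit))
  separation <- any(probs > 1 - 1e-8) || any(probs < 1e-8) || !fit$converged
  coefs <- stats::coef(fit)
  notes <- character(0)
  if (separation && length(current) > 0) {
    coefs <- ridge_logistic(cbind(1, Z[, current, drop = FALSE]), labels, lambda = 1e-2)
    names(coefs) <- c("(Intercept)", current)
    probs <- as.numeric(stats::plogis(cbind(1, Z[, current, drop = FALSE]) %*% coefs))
    notes <- "separation detected; coefficients from ridge-penalized IRLS"
  }

  structure(
    list(endpoint = endpoint,
         features = current,
         center = centers[current], scale = scales[current],
         intercept = unname(coefs["(Intercept)"]),
         coefficients = coefs[setdiff(names(coefs), "(Intercept)")],
         aic = stats::AIC(fit),
         log_likelihood = as.numeric(stats::logLik(fit)),
         n_parameters = length(current) + 1L,
         separation = separation,
         risk_cutoff = stats::median(probs),
         training_auc = if (length(current)) auc_mw(probs, labels) else 0.5,
         notes = notes),
    class = "prognostic_model"
  )
}

# Ridge-penalized logistic IRLS (intercept unpenalized); fallback used only
# under complete separation.
ridge_logistic <- function(X, y, lambda = 1e-2, iter = 50) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (it in seq_len(iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.numeric(beta)
}

#' @export
print.prognostic_model <- function(x, ...) {
  ep <- if (!is.null(x$endpoint$outcome) && !is.na(x$endpoint$outcome)) {
    sprintf(" %s at %s months (%s)", x$endpoint$outcome,
            x$endpoint$horizon_months, x$endpoint$feature_set)
  } else ""
  cat(sprintf("<prognostic_model>%s [%d features]\n", ep, length(x$features)))
  if (length(x$features) == 0) {
    cat("  intercept-only null model\n")
  } else {
    cat("  selected:", paste(x$features, collapse = ", "), "\n")
  }
  cat(sprintf("  AIC %.2f | training AUC %.3f | cutoff %.3f%s\n", x$aic,
              x$training_auc, x$risk_cutoff,
              if (x$separation) " | separation flagged" else ""))
  invisible(x)
}

#' @export
predict.prognostic_model <- function(object, newdata, ...) {
  if (length(object$features) == 0) {
    return(rep(stats::plogis(object$intercept), nrow(newdata)))
  }
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) stop_petrad("newdata lacks feature(s): ",
                                   paste(missing, collapse = ", "))
  Z <- sweep(sweep(as.matrix(newdata[object$features]), 2, object$center),
             2, object$scale, `/`)
  as.numeric(stats::plogis(object$intercept + Z %*% object$coefficients))
}

#' Full selection pipeline on one training table
#'
#' Horn parallel analysis -> PCA grouping -> per-group univariable AUC
#' screening -> backward-AIC logistic fit. This is the unit re-run inside
#' every cross-validation fold.
#'
#' @param data feature tibble (`patient_id` ignored).
#' @param labels 0/1 labels.
#' @param endpoint endpoint description list.
#' @param horn_reps,horn_quantile Horn parallel-analysis parameters.
#' @param alpha univariable significance level.
#' @param seed seed for the Horn reference datasets.
#' @return A `prognostic_model` (with the screening table in `$screening`).
#' @export
fit_prognostic_pipeline <- function(data, labels,
                                    endpoint = list(outcome = NA,
                                                    horizon_months = NA,
                                                    feature_set = NA),
                                    horn_reps = 1000, horn_quantile = 0.95,
                                    alpha = 0.05, seed = 1L) {
  if (is.data.frame(data)) data <- data[, setdiff(names(data), "patient_id"), drop = FALSE]
  sds <- vapply(data, stats::sd, numeric(1))
  usable <- names(data)[sds > 0 & is.finite(sds)]
  if (length(usable) < 2) {
    model <- fit_backward_aic(data, labels, character(0), endpoint)
    model$screening <- tibble::tibble()
    return(model)
  }
  dat <- data[usable]
  k <- horn_components(dat, n_reps = horn_reps, quantile = horn_quantile,
                       seed = seed)
  groups <- suppressWarnings(group_features(dat, k))
  screen <- univariable_screen(dat, labels, groups, alpha = alpha)
  model <- fit_backward_aic(dat, labels, screen$feature[screen$candidate], endpoint)
  model$n_components <- k
  model$screening <- screen
  model
}

#' Stratified k-fold cross-validation of the whole pipeline
#'
#' The complete selection pipeline (Horn -> grouping -> screening ->
#' backward AIC) is re-fit inside each training fold and evaluated on the
#' held-out fold, so feature selection never sees validation data.
#'
#' @inheritParams fit_prognostic_pipeline
#' @param k number of folds.
#' @param seed fold-assignment (and Horn) seed.
#' @return List `fold_auc`, `cv_auc_mean`, `cv_auc_range`.
#' @export
cross_validate <- function(data, labels, k = 5, seed = 1L,
                           horn_reps = 1000, alpha = 0.05) {
  labels <- as.integer(labels)
  if (min(sum(labels == 1), sum(labels == 0)) < k) {
    stop_petrad("fewer than k = ", k, " patients in one class; use a smaller k")
  }
  if (is.data.frame(data)) data <- data[, setdiff(names(data), "patient_id"), drop = FALSE]
  folds <- integer(length(labels))
  folds[labels == 1] <- with_seed(seed, sample(rep_len(seq_len(k), sum(labels == 1))))
  folds[labels == 0] <- with_seed(derive_seed(seed, "ctrl"),
                                  sample(rep_len(seq_len(k), sum(labels == 0))))
  fold_auc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    model <- fit_prognostic_pipeline(data[tr, , drop = FALSE], labels[tr],
                                     horn_reps = horn_reps, alpha = alpha,
                                     seed = derive_seed(seed, paste0("fold", f)))
    if (length(model$features) == 0) return(0.5)
    auc_mw(predict(model, data[!tr, , drop = FALSE]), labels[!tr])
  }, numeric(1))
  list(fold_auc = fold_auc, cv_auc_mean = mean(fold_auc),
       cv_auc_range = max(fold_auc) - min(fold_auc))
}

#' Pick the best model by the mean/range trade-off
#'
#' Ranks models by `cv_auc_mean - lambda * cv_auc_range` (largest average
#' cross-validated AUC, penalizing unstable folds); exact ties break by the
#' higher mean, then by lexicographic endpoint id.
#'
#' @param models tibble with columns `endpoint_id`, `cv_auc_mean`,
#'   `cv_auc_range` (one row per candidate model).
#' @param lambda trade-off weight.
#' @return The input tibble with `score`, sorted; best model first.
#' @export
select_best <- function(models, lambda = 0.5) {
  if (nrow(models) == 0) stop_petrad("empty model list")
  models |>
    dplyr::mutate(score = .data$cv_auc_mean - lambda * .data$cv_auc_range) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$cv_auc_mean),
                   .data$endpoint_id)
}

#' External validation of a frozen model
#'
#' Applies a trained model (frozen standardization and coefficients) to a
#' validation table and reports AUC with a DeLong 95% confidence interval.
#'
#' @param model a `prognostic_model`.
#' @param data validation feature tibble.
#' @param labels validation 0/1 labels.
#' @return List `auc`, `ci95` (length 2), `probs`.
#' @export
validate_model <- function(model, data, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop_petrad("validation labels contain one class")
  probs <- predict(model, data)
  a <- auc_mw(probs, labels)
  ci <- if (stats::var(probs) == 0) {
    c(NA_real_, NA_real_)
  } else {
    as.numeric(pROC::ci.auc(pROC::roc(labels, probs, quiet = TRUE,
                                      direction = "<"), method = "delong"))[c(1, 3)]
  }
  list(auc = a, ci95 = ci, probs = probs)
}

#' Kaplan–Meier risk stratification with a G-rho test
#'
#' Splits patients into low/high-risk groups at the training-cohort median
#' predicted probability (reused verbatim for validation data), fits
#' Kaplan–Meier curves per group, and tests the split with the
#' Harrington–Fleming G-rho family (rho = 0 is the log-rank test).
#'
#' @param model a `prognostic_model`.
#' @param data feature tibble for the cohort being stratified.
#' @param outcomes matching survival table.
#' @param outcome `"efs"` or `"os"`.
#' @param rho G-rho weight exponent.
#' @param cutoff risk cutoff; defaults to the model's training median.
#' @return A `km_stratification` list: `groups`, `curves` (tidy KM tibble),
#'   `median_survival` per group, `p_value`, `chisq`, `cutoff`.
#' @export
stratify_km <- function(model, data, outcomes, outcome = c("efs", "os"),
                        rho = 0, cutoff = NULL) {
  outcome <- match.arg(outcome)
  cutoff <- cutoff %||% model$risk_cutoff
  probs <- predict(model, data)
  grp <- factor(ifelse(probs > cutoff, "high_risk", "low_risk"),
                levels = c("low_risk", "high_risk"))
  if (length(unique(grp)) < 2) {
    stop_petrad("all patients fall on one side of the risk cutoff")
  }
  tm <- outcomes[[paste0(outcome, "_months")]]
  ev <- outcomes[[paste0(outcome, "_event")]]
  sf <- survival::survfit(survival::Surv(tm, ev) ~ grp)
  sd_ <- survival::survdiff(survival::Surv(tm, ev) ~ grp, rho = rho)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  strata_lab <- rep(sub("^grp=", "", names(sf$strata)), sf$strata)
  curves <- tibble::tibble(group = strata_lab, time = sf$time,
                           n_risk = sf$n.risk, n_event = sf$n.event,
                           survival = sf$surv)
  med <- curves |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(median_months = {
      below <- .data$time[.data$survival <= 0.5]
      if (length(below)) min(below) else NA_real_
    }, .groups = "drop")
  structure(list(groups = grp, curves = curves, median_survival = med,
                 p_value = p, chisq = sd_$chisq, rho = rho, cutoff = cutoff),
            class = "km_stratification")
}

#' Prognostic-and-stable feature overlap
#'
#' Features with oriented univariable AUC > `auc_threshold` in both the
#' training and validation cohorts form the prognostic set; the overlap
#' reports what percentage of that set is stable against each robustness
#' factor.
#'
#' @param train_data,train_labels training features and 0/1 labels.
#' @param valid_data,valid_labels validation features and labels.
#' @param stability tibble with `feature` plus one logical column per factor
#'   (e.g. `delineation`, `attenuation`, `motion`).
#' @param auc_threshold prognostic AUC threshold.
#' @return List `prognostic_features`, `pct_stable` (named per factor; `NA`
#'   with `empty = TRUE` when no feature is prognostic in both cohorts).
#' @export
prognostic_overlap <- function(train_data, train_labels, valid_data,
                               valid_labels, stability, auc_threshold = 0.6) {
  feats <- intersect(setdiff(names(train_data), "patient_id"),
                     setdiff(names(valid_data), "patient_id"))
  auc_tr <- vapply(feats, function(f) auc_mw(train_data[[f]], train_labels,
                                             orient = TRUE), numeric(1))
  auc_va <- vapply(feats, function(f) auc_mw(valid_data[[f]], valid_labels,
                                             orient = TRUE), numeric(1))
  prog <- feats[auc_tr > auc_threshold & auc_va > auc_threshold]
  factors <- setdiff(names(stability), c("feature", "family"))
  if (length(prog) == 0) {
    return(list(prognostic_features = character(0),
                pct_stable = stats::setNames(rep(NA_real_, length(factors)), factors),
                empty = TRUE))
  }
  st <- stability[match(prog, stability$feature), , drop = FALSE]
  pct <- vapply(factors, function(fc) 100 * mean(st[[fc]], na.rm = TRUE), numeric(1))
  list(prognostic_features = prog, pct_stable = pct, empty = FALSE)
}
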