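#' Endpoint binarization
#'
#' Converts a survival outcome table into binary labels at a horizon: an
#' event at or before the horizon is the event class, event-free follow-up
#' reaching the horizon the non-event class. Patients censored before the
#' horizon carry no label; by default they are excluded (`censored =
#' "exclude"`), optionally treated as non-events.
#'
#' @param outcomes tibble with `patient_id`, `<outcome>_months`,
#'   `<outcome>_event` columns (as produced by the cohort generators).
#' @param outcome `"efs"` or `"os"`.
#' @param horizon_months horizon, typically 12, 18 or 24.
#' @param censored `"exclude"` or `"nonevent"`.
#' @return Tibble `patient_id`, `label` (0/1); excluded patients are dropped
#'   and counted in attribute `n_excluded`.
#' @export
binarize_outcomes <- function(outcomes, outcome = c("efs", "os"),
                              horizon_months = 12,
                              censored = c("exclude", "nonevent")) {
  outcome <- match.arg(outcome)
  censored <- match.arg(censored)
  tm <- outcomes[[paste0(outcome, "_months")]]
  ev <- outcomes[[paste0(outcome, "_event")]]
  if (is.null(tm) || is.null(ev)) stop_petrad("outcome columns not found for ", outcome)
  if (any(tm < 0)) stop_petrad("negative survival times")
  label <- dplyr::case_when(
    ev == 1 & tm <= horizon_months ~ 1L,
    tm >= horizon_months ~ 0L,
    TRUE ~ NA_integer_  # censored before horizon
  )
  if (censored == "nonevent") label[is.na(label)] <- 0L
  out <- tibble::tibble(patient_id = outcomes$patient_id, label = label)
  n_excl <- sum(is.na(label))
  out <- out[!is.na(out$label), ]
  attr(out, "n_excluded") <- n_excl
  out
}

#' Horn's parallel analysis
#'
#' Number of principal components of the (standardized) data whose
#' correlation-matrix eigenvalues exceed the chosen quantile of rank-matched
#' eigenvalues from `n_reps` standard-normal datasets of identical shape.
#'
#' @param data numeric matrix or feature tibble (a `patient_id` column is
#'   dropped); constant columns are removed with a warning.
#' @param n_reps number of random reference datasets.
#' @param quantile reference quantile (0.95 default).
#' @param seed RNG seed for the reference datasets.
#' @return Integer number of retained components (at least 1).
#' @export
horn_components <- function(data, n_reps = 1000, quantile = 0.95, seed = 1L) {
  X <- as_feature_matrix(data)
  if (ncol(X) < 2) stop_petrad("Horn parallel analysis needs >= 2 features")
  if (n_reps < 1) stop_petrad("`n_reps` must be positive")
  n <- nrow(X); p <- ncol(X)
  ev_data <- corr_eigenvalues(X)
  m <- min(n - 1, p)
  ref <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      corr_eigenvalues(matrix(stats::rnorm(n * p), n, p))[seq_len(m)]
    }, numeric(m))
  })
  thr <- apply(ref, 1, stats::quantile, probs = quantile, names = FALSE)
  # Sequential rule: retain leading components while each exceeds its
  # rank-matched reference quantile.
  exceeds <- ev_data[seq_len(m)] > thr
  retained <- if (all(exceeds)) m else which(!exceeds)[1] - 1L
  max(1L, as.integer(retained))
}

corr_eigenvalues <- function(X) {
  Xs <- scale(X)
  d <- svd(Xs, nu = 0, nv = 0)$d
  ev <- d^2 / (nrow(X) - 1)
  c(ev, rep(0, max(0, ncol(X) - length(ev))))
}

as_feature_matrix <- function(data, drop_constant = TRUE) {
  if (is.data.frame(data)) data <- data[, setdiff(names(data), "patient_id"), drop = FALSE]
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (drop_constant) {
    const <- apply(X, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
    if (any(const)) {
      warning(sum(const), " constant feature(s) dropped", call. = FALSE)
      X <- X[, !const, drop = FALSE]
    }
  }
  X
}

#' Group features by their dominant principal component
#'
#' Features are standardized, a PCA is fit, and each feature is assigned to
#' the retained component whose score it correlates with most strongly (in
#' absolute value). Zero-variance features go to the sentinel group 0 and
#' are excluded downstream.
#'
#' @param data feature tibble or matrix.
#' @param n_components number of retained components (from
#'   [horn_components()]).
#' @return Tibble `feature`, `group` (integer; 0 = degenerate).
#' @export
group_features <- function(data, n_components) {
  if (is.data.frame(data)) data <- data[, setdiff(names(data), "patient_id"), drop = FALSE]
  X <- as.matrix(data)
  feats <- colnames(X)
  sds <- apply(X, 2, stats::sd)
  ok <- sds > 0 & is.finite(sds)
  if (!all(ok)) warning(sum(!ok), " zero-variance feature(s) assigned to group 0",
                        call. = FALSE)
  n_components <- min(n_components, sum(ok), nrow(X) - 1)
  pc <- stats::prcomp(X[, ok, drop = FALSE], center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  cr <- abs(stats::cor(X[, ok, drop = FALSE], scores))
  grp <- integer(length(feats))
  grp[ok] <- apply(cr, 1, which.max)
  tibble::tibble(feature = feats, group = grp)
}

#' Mann–Whitney AUC
#'
#' Area under the ROC curve computed as the normalized Mann–Whitney U
#' statistic (midranks; ties count 1/2), equal to the proportion of
#' case–control pairs ranked concordantly.
#'
#' @param x numeric scores.
#' @param labels 0/1 labels (1 = case).
#' @param orient if `TRUE`, returns `max(auc, 1 - auc)`.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(x, labels, orient = FALSE) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_petrad("AUC needs both classes present")
  r <- rank(x)
  a <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orient) max(a, 1 - a) else a
}

#' Univariable per-group screening
#'
#' Within each feature group, the feature with the largest oriented
#' univariable AUC is the group surrogate; it is retained as a model
#' candidate only if its single-feature logistic Wald p-value is below
#' `alpha`. Ties in AUC break lexicographically by feature name.
#'
#' @param data feature tibble (a `patient_id` column is ignored).
#' @param labels 0/1 outcome labels aligned with rows of `data`.
#' @param groups grouping tibble from [group_features()].
#' @param alpha significance level for the Wald test.
#' @return Tibble `feature`, `group`, `auc`, `p_value`, `candidate`.
#' @export
univariable_screen <- function(data, labels, groups, alpha = 0.05) {
  if (length(unique(labels)) < 2) stop_petrad("labels contain a single class")
  if (is.data.frame(data)) data <- data[, setdiff(names(data), "patient_id"), drop = FALSE]
  res <- groups |>
    dplyr::filter(.data$group > 0) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(g, key) {
      aucs <- vapply(g$feature, function(f) auc_mw(data[[f]], labels, orient = TRUE),
                     numeric(1))
      best <- g$feature[order(-aucs, g$feature)][1]
      fit <- suppressWarnings(stats::glm(labels ~ x, family = stats::binomial(),
                                         data = data.frame(x = data[[best]], labels = labels)))
      p <- summary(fit)$coefficients
      pv <- if ("x" %in% rownames(p)) p["x", "Pr(>|z|)"] else 1
      tibble::tibble(feature = best, auc = max(aucs), p_value = pv)
    }) |>
    dplyr::ungroup()
  res$candidate <- res$p_value < alpha
  res[, c("feature", "group", "auc", "p_value", "candidate")]
}
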