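#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a prognostic model
#'
#' @param x a `prognostic_model`.
#' @param ... unused.
#' @return One row per selected feature with its standardized log-odds
#'   coefficient (plus the intercept).
#' @export
tidy.prognostic_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$features),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @rdname tidy.prognostic_model
#' @return `glance()`: one-row model summary (AIC, log-likelihood, training
#'   AUC, risk cutoff, separation flag).
#' @export
glance.prognostic_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    aic = x$aic,
    log_likelihood = x$log_likelihood,
    training_auc = x$training_auc,
    risk_cutoff = x$risk_cutoff,
    separation = x$separation
  )
}

#' Plot per-family feature stability
#'
#' Bar chart of the percentage of stable features per feature family for one
#' or more robustness studies.
#'
#' @param results a single [run_study()] tibble or a named list of them.
#' @return A ggplot object.
#' @export
plot_family_stability <- function(results) {
  if (is.data.frame(results)) {
    results <- stats::setNames(list(results), attr(results, "study") %||% "study")
  }
  df <- purrr::imap_dfr(results, function(r, nm) {
    dplyr::mutate(family_stability(r), study = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$pct_stable,
                                   fill = .data$family)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~study) +
    ggplot2::labs(x = NULL, y = "stable features (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @rdname stratify_km
#' @param object a `km_stratification`.
#' @param ... unused.
#' @export
autoplot.km_stratification <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "months", y = "survival probability",
                  subtitle = sprintf("G-rho (rho = %g) p = %.3g",
                                     object$rho, object$p_value)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
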