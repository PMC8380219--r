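#' Intraclass correlation coefficients
#'
#' Shrout–Fleiss intraclass correlations for a complete subjects x
#' raters/conditions matrix, in the three forms used for feature-robustness
#' screening: one-way random single measures ICC(1,1), two-way mixed
#' consistency single measures ICC(3,1), and two-way mixed average measures
#' ICC(3,k). Computed from the ANOVA mean squares: with BMS the
#' between-subject, WMS the within-subject and EMS the residual mean square,
#'
#' * ICC(1,1) = (BMS - WMS) / (BMS + (k-1) WMS)
#' * ICC(3,1) = (BMS - EMS) / (BMS + (k-1) EMS)
#' * ICC(3,k) = (BMS - EMS) / BMS
#'
#' A matrix whose entries are all identical has no variance to apportion and
#' is defined as ICC = 1 (perfect agreement) with a warning.
#'
#' @param data numeric matrix, subjects in rows, raters/conditions in columns;
#'   at least 2 of each, no missing cells.
#' @param form `"ICC_1_1"`, `"ICC_3_1"` or `"ICC_3_k"`.
#' @param warn emit the constant-matrix warning (silenced in batch screening).
#' @return The ICC as a single number in (-Inf, 1].
#' @export
icc <- function(data, form = c("ICC_1_1", "ICC_3_1", "ICC_3_k"), warn = TRUE) {
  form <- match.arg(form)
  data <- as.matrix(data)
  if (any(is.na(data))) stop_petrad("ICC requires complete data (no missing cells)")
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop_petrad("ICC needs >= 2 subjects and >= 2 raters")

  row_m <- rowMeans(data); col_m <- colMeans(data); gm <- mean(data)
  if (all(abs(data - gm) < .Machine$double.eps^0.5 * max(1, abs(gm)))) {
    if (warn) warning("all values identical; ICC defined as 1", call. = FALSE)
    return(1)
  }
  bms <- k * sum((row_m - gm)^2) / (n - 1)
  wms <- sum(sweep(data, 1, row_m)^2) / (n * (k - 1))
  ems <- sum((data - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + gm)^2) / ((n - 1) * (k - 1))
  switch(form,
         ICC_1_1 = (bms - wms) / (bms + (k - 1) * wms),
         ICC_3_1 = (bms - ems) / (bms + (k - 1) * ems),
         ICC_3_k = (bms - ems) / bms)
}
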