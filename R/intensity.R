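#' First-order intensity features
#'
#' Seventeen first-order statistics of the ROI intensities. Moments use the
#' population (n-denominator) convention; kurtosis is excess kurtosis;
#' entropy and uniformity are computed on the fixed-bin-size histogram (the
#' same discretization the texture matrices use). For a constant ROI the
#' scale-free statistics (skewness, kurtosis, coefficient of variation) are
#' defined as 0 rather than NaN.
#'
#' @param x numeric vector of ROI intensities.
#' @param bin_size histogram bin width for entropy/uniformity.
#' @param bin_idx optional precomputed integer bin indices for `x`; when
#'   `NULL`, bins are anchored at 0 (`floor(x / bin_size) + 1`).
#' @param prefix name prefix for the returned features.
#' @return Named numeric vector of length 17.
#' @export
intensity_features <- function(x, bin_size = 0.25, bin_idx = NULL,
                               prefix = "intensity/suv/") {
  if (length(x) < 1) stop_petrad("empty intensity sample")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sdv <- sqrt(m2)
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else 0
  cv <- if (sdv > 0 && mu != 0) sdv / mu else 0
  qs <- stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  if (is.null(bin_idx)) bin_idx <- pmax(floor(x / bin_size), 0) + 1L
  p <- tabulate(bin_idx) / n
  p <- p[p > 0]
  out <- c(
    mean = mu,
    variance = m2,
    skewness = skew,
    kurtosis = kurt,
    median = stats::median(x),
    minimum = min(x),
    maximum = max(x),
    range = max(x) - min(x),
    percentile_10 = qs[1],
    percentile_90 = qs[4],
    interquartile_range = qs[3] - qs[2],
    mean_absolute_deviation = mean(abs(x - mu)),
    energy = sum(x^2),
    root_mean_square = sqrt(mean(x^2)),
    coefficient_of_variation = cv,
    entropy = -sum(p * log2(p)),
    uniformity = sum(p^2)
  )
  names(out) <- paste0(prefix, names(out))
  out
}
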