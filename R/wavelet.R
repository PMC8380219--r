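#' Undecimated 3D Haar wavelet decomposition
#'
#' One-level separable, undecimated (stationary) Haar transform. Each axis is
#' filtered with a two-tap low-pass (`L`) or high-pass (`H`) filter; the 8
#' subbands are labelled by the per-axis filters in axis order, first letter =
#' x-axis, last = z-axis (so `"HLL"` is high-pass along x). No downsampling
#' is applied, so every subband lives on the input grid and the ROI mask can
#' be reused unchanged. The edge sample is extended symmetrically.
#'
#' With `normalization = "unit"` (default for feature extraction) the
#' low-pass filter has unit gain, so the LLL subband of a constant volume is
#' that constant. `normalization = "ortho"` uses the orthonormal Haar pair
#' `(1/sqrt(2), 1/sqrt(2))`, under which the summed energy of the 8 subbands
#' equals the input energy (up to edge handling).
#'
#' @param vol an [image_volume()].
#' @param normalization `"unit"` or `"ortho"`.
#' @return Named list of 8 `image_volume`s, in order
#'   LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH.
#' @export
wavelet_decompose <- function(vol, normalization = c("unit", "ortho")) {
  stopifnot(inherits(vol, "image_volume"))
  normalization <- match.arg(normalization)
  gain <- if (normalization == "unit") 0.5 else 1 / sqrt(2)
  x <- vol$values
  filt <- function(a, axis, kind) {
    nxt <- next_sample(a, axis)
    if (kind == "L") gain * (a + nxt) else gain * (a - nxt)
  }
  labels <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- lapply(labels, function(lab) {
    f <- strsplit(lab, "")[[1]]  # lab[1] = x filter, lab[3] = z filter
    a <- filt(x, 1, f[1])
    a <- filt(a, 2, f[2])
    a <- filt(a, 3, f[3])
    image_volume(a, vol$spacing_mm, vol$origin_mm, "WAVELET")
  })
  stats::setNames(out, labels)
}

# x shifted by +1 along `axis` with symmetric (edge-replicate) extension.
next_sample <- function(x, axis) {
  n <- dim(x)[axis]
  idx <- c(seq_len(n - 1) + 1L, n)
  switch(axis,
         `1` = x[idx, , , drop = FALSE],
         `2` = x[, idx, , drop = FALSE],
         `3` = x[, , idx, drop = FALSE])
}
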