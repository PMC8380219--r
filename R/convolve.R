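# Separable convolution machinery used by the phantom generator, the motion
# model and the shape surface estimator.

gaussian_kernel <- function(sigma_vox, truncate = 3.5) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# Convolve a 3D array along one axis with a symmetric kernel.
# pad = "zero" extends with zeros (mass-preserving on a padded grid),
# pad = "replicate" extends with the edge value.
convolve_axis <- function(x, kernel, axis, pad = c("zero", "replicate")) {
  pad <- match.arg(pad)
  if (length(kernel) == 1) return(x * kernel)
  r <- (length(kernel) - 1L) / 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  xp <- aperm(x, perm)
  d <- dim(xp)
  m <- matrix(xp, nrow = d[1])
  n <- d[1]
  if (pad == "zero") {
    top <- matrix(0, nrow = r, ncol = ncol(m))
    mp <- rbind(top, m, top)
  } else {
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  }
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  aperm(array(out, dim = d), order(perm))
}

# Isotropic-or-not Gaussian smoothing with per-axis sigma in voxels.
smooth_gaussian <- function(x, sigma_vox, pad = "zero") {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      x <- convolve_axis(x, gaussian_kernel(sigma_vox[ax]), ax, pad = pad)
    }
  }
  x
}

# Smooth, standardized Gaussian random field: white noise filtered with a
# Gaussian of correlation length `scale_mm`, rescaled to mean 0 / sd 1 over
# the grid. Deterministic under `seed`.
gaussian_random_field <- function(grid_shape, spacing_mm, scale_mm, seed) {
  noise <- with_seed(seed, array(stats::rnorm(prod(grid_shape)), dim = grid_shape))
  sigma_vox <- rep(scale_mm, 3) / spacing_mm
  f <- smooth_gaussian(noise, sigma_vox, pad = "replicate")
  (f - mean(f)) / stats::sd(f)
}
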