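#' Perturbation models for the robustness studies
#'
#' Three perturbation families emulate the paired-acquisition robustness
#' studies of a PET radiomics workflow: (i) delineation variability (three
#' contouring styles), (ii) attenuation-correction differences (a smooth
#' multiplicative bias field), and (iii) respiratory motion (anisotropic
#' Gaussian blur standing in for free-breathing averaging; the unblurred
#' volume plays the gated role).
#'
#' @name perturbations
NULL

# 26-connected region growing from a seed voxel over a logical eligibility map.
grow_region <- function(eligible, seed_idx) {
  n <- dim(eligible)
  lab <- array(FALSE, dim = n)
  if (!eligible[seed_idx[1], seed_idx[2], seed_idx[3]]) return(lab)
  offs <- all_offsets_3d()
  queue <- matrix(seed_idx, ncol = 3)
  lab[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue
    queue <- matrix(integer(0), ncol = 3)
    for (k in seq_len(nrow(offs))) {
      nb <- sweep(cur, 2, offs[k, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= n[1] & nb[, 2] >= 1 & nb[, 2] <= n[2] &
        nb[, 3] >= 1 & nb[, 3] <= n[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) next
      el <- eligible[nb] & !lab[nb]
      nb <- nb[el, , drop = FALSE]
      if (nrow(nb) == 0) next
      lab[nb] <- TRUE
      queue <- rbind(queue, nb)
    }
    if (nrow(queue) > 0) queue <- unique(queue)
  }
  lab
}

mask_centroid_idx <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  round(colMeans(idx))
}

#' @describeIn perturbations Three delineation variants of a tumour mask:
#'   a seeded "manual-like" boundary perturbation (one-voxel dilation on a
#'   random half of the boundary), a connected SUV-threshold region at
#'   `threshold_pct` of SUVmax, and a "gradient-like" contour at the radius
#'   of maximal SUV gradient magnitude. The threshold fraction must lie in
#'   the clinically used 0.27--0.41 band.
#' @param pet an SUV [image_volume()].
#' @param mask the reference [roi_mask()].
#' @param threshold_pct threshold fraction of SUVmax, in `[0.27, 0.41]`.
#' @param seed integer seed for the manual-like boundary perturbation.
#' @return `delineation_variants()`: named list of three `roi_mask`s
#'   (`manual`, `threshold`, `gradient`).
#' @export
delineation_variants <- function(pet, mask, threshold_pct = 0.35, seed = 1L) {
  stopifnot(inherits(pet, "image_volume"), inherits(mask, "roi_mask"))
  if (!same_geometry(pet, mask)) stop_petrad("PET and mask geometry mismatch")
  if (threshold_pct < 0.27 || threshold_pct > 0.41) {
    stop_petrad("`threshold_pct` must lie in [0.27, 0.41], got ", threshold_pct)
  }
  m <- mask$values
  n <- dim(m)

  # Manual-like: dilate a random half of the outer boundary shell.
  shell <- array(FALSE, dim = n)
  for (k in seq_len(nrow(all_offsets_3d()))) {
    d <- all_offsets_3d()[k, ]
    if (sum(abs(d)) != 1) next  # 6-connected shell
    shell <- shell | (!m & shift_array(m, d, fill = FALSE))
  }
  cand <- which(shell)
  pick <- with_seed(seed, sample(cand, size = floor(length(cand) / 2)))
  manual <- m
  manual[pick] <- TRUE

  # Threshold-based: connected region >= pct * SUVmax, grown from the
  # hottest tumour voxel (which is eligible by construction).
  suvmax <- max(pet$values[m])
  eligible <- pet$values >= threshold_pct * suvmax
  hot <- which(m & pet$values == suvmax, arr.ind = TRUE)[1, ]
  thresh <- grow_region(eligible, hot)
  if (!any(thresh)) {
    stop_petrad("empty region at threshold ", threshold_pct, " x SUVmax")
  }

  # Gradient-like: radial position of maximal mean gradient magnitude.
  sp <- pet$spacing_mm
  g <- smooth_gaussian(pet$values, rep(1, 3), pad = "replicate")
  gx <- (shift_array(g, c(1L, 0L, 0L), 0) - shift_array(g, c(-1L, 0L, 0L), 0)) / (2 * sp[1])
  gy <- (shift_array(g, c(0L, 1L, 0L), 0) - shift_array(g, c(0L, -1L, 0L), 0)) / (2 * sp[2])
  gz <- (shift_array(g, c(0L, 0L, 1L), 0) - shift_array(g, c(0L, 0L, -1L), 0)) / (2 * sp[3])
  gmag <- sqrt(gx^2 + gy^2 + gz^2)
  ci <- mask_centroid_idx(mask)
  centre_mm <- (ci - 1) * sp
  cx <- axis_coords(n[1], sp[1], 0) - centre_mm[1]
  cy <- axis_coords(n[2], sp[2], 0) - centre_mm[2]
  cz <- axis_coords(n[3], sp[3], 0) - centre_mm[3]
  r <- sqrt(outer(outer(cx^2, cy^2, `+`), cz^2, `+`))
  bw <- min(sp)
  rb <- floor(r / bw)
  rmax_bin <- floor(max(r[m]) * 1.5 / bw)
  keep <- rb <= rmax_bin & rb >= 1
  prof <- tapply(gmag[keep], rb[keep], mean)
  r_star <- (as.numeric(names(prof)[which.max(prof)]) + 0.5) * bw
  gradient <- r <= r_star

  list(
    manual = roi_mask(manual, sp, mask$origin_mm),
    threshold = roi_mask(thresh, sp, mask$origin_mm),
    gradient = roi_mask(gradient, sp, mask$origin_mm)
  )
}

#' @describeIn perturbations Smooth multiplicative attenuation-style bias:
#'   the PET volume is multiplied voxelwise by `1 + bias_strength * f` where
#'   `f` is a zero-mean, unit-sd Gaussian random field with correlation
#'   length `scale_mm`; the field is floored at 0.05 so intensities stay
#'   positive. The mask is untouched.
#' @param bias_strength relative bias amplitude, in `[0, 0.5]`.
#' @param scale_mm correlation length of the bias field.
#' @return `attenuation_variant()`: the biased `image_volume`.
#' @export
attenuation_variant <- function(pet, bias_strength = 0.25, seed = 1L,
                                scale_mm = 40) {
  stopifnot(inherits(pet, "image_volume"))
  if (bias_strength < 0 || bias_strength > 0.5) {
    stop_petrad("`bias_strength` must lie in [0, 0.5]")
  }
  if (bias_strength == 0) return(pet)
  f <- gaussian_random_field(dim(pet$values), pet$spacing_mm, scale_mm, seed)
  bias <- pmax(1 + bias_strength * f, 0.05)
  # Attenuation differences redistribute regional contrast rather than
  # rescaling average activity: normalize to unit mean bias over the central
  # half of the grid (where the lesion sits).
  n <- dim(bias)
  ctr <- lapply(n, function(k) seq(floor(k / 4) + 1, ceiling(3 * k / 4)))
  bias <- bias / mean(bias[ctr[[1]], ctr[[2]], ctr[[3]]])
  image_volume(pet$values * bias, pet$spacing_mm, pet$origin_mm, pet$modality)
}

#' @describeIn perturbations Respiratory-blur surrogate: anisotropic Gaussian
#'   smoothing with per-axis FWHM in mm (dominant axis mimics the
#'   cranio-caudal breathing direction). The kernel is normalized so total
#'   uptake is conserved up to boundary truncation; the mask is untouched.
#' @param blur_fwhm_mm length-3 non-negative FWHM in mm.
#' @return `motion_variant()`: the blurred `image_volume`.
#' @export
motion_variant <- function(pet, blur_fwhm_mm = c(4, 4, 12)) {
  stopifnot(inherits(pet, "image_volume"))
  if (length(blur_fwhm_mm) != 3 || any(blur_fwhm_mm < 0)) {
    stop_petrad("`blur_fwhm_mm` must be 3 non-negative values")
  }
  sigma_vox <- blur_fwhm_mm / (2 * sqrt(2 * log(2))) / pet$spacing_mm
  out <- smooth_gaussian(pet$values, sigma_vox, pad = "zero")
  image_volume(out, pet$spacing_mm, pet$origin_mm, pet$modality)
}
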