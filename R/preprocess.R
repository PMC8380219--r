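#' Preprocessing: resampling, HU exclusion, size gate, discretization
#'
#' Raw PET/CT/mask triplets are (1) resampled to a common cubic grid (5.5 mm
#' by default) with trilinear interpolation, (2) filtered with a CT
#' Hounsfield-unit window (-300..200 by default, inclusive) that removes lung
#' and bone voxels from the ROI, (3) gated on a minimum ROI size of 72 voxels
#' so wavelet texture remains meaningful, and (4) discretized with a fixed
#' 0.25 SUV bin width anchored at SUV 0.
#'
#' @name preprocessing
NULL

# Vectorized trilinear interpolation of `values` at physical points given by
# per-axis coordinate vectors (a full grid). Points outside the voxel-centre
# range are clamped to the edge.
interp_trilinear_grid <- function(values, spacing, origin, qx, qy, qz) {
  n <- dim(values)
  cont <- function(q, ax) pmin(pmax((q - origin[ax]) / spacing[ax] + 1, 1), n[ax])
  fx <- cont(qx, 1); fy <- cont(qy, 2); fz <- cont(qz, 3)
  ix <- pmin(floor(fx), n[1] - 1L); wx <- fx - ix
  iy <- pmin(floor(fy), n[2] - 1L); wy <- fy - iy
  iz <- pmin(floor(fz), n[3] - 1L); wz <- fz - iz
  if (n[1] == 1) { ix <- rep(1, length(fx)); wx <- rep(0, length(fx)) }
  if (n[2] == 1) { iy <- rep(1, length(fy)); wy <- rep(0, length(fy)) }
  if (n[3] == 1) { iz <- rep(1, length(fz)); wz <- rep(0, length(fz)) }
  nq <- c(length(qx), length(qy), length(qz))
  IX <- array(rep(ix, times = nq[2] * nq[3]), dim = nq)
  WX <- array(rep(wx, times = nq[2] * nq[3]), dim = nq)
  IY <- array(rep(rep(iy, each = nq[1]), times = nq[3]), dim = nq)
  WY <- array(rep(rep(wy, each = nq[1]), times = nq[3]), dim = nq)
  IZ <- array(rep(iz, each = nq[1] * nq[2]), dim = nq)
  WZ <- array(rep(wz, each = nq[1] * nq[2]), dim = nq)
  out <- array(0, dim = nq)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) WX else 1 - WX) * (if (dy == 1) WY else 1 - WY) *
      (if (dz == 1) WZ else 1 - WZ)
    xi <- pmin(IX + dx, n[1]); yi <- pmin(IY + dy, n[2]); zi <- pmin(IZ + dz, n[3])
    out <- out + w * values[cbind(c(xi), c(yi), c(zi))]
  }
  out
}

resampled_axis <- function(n, spacing, origin, target) {
  extent <- (n - 1) * spacing
  n_new <- floor(extent / target + 1e-9) + 1L
  list(n = n_new, coords = origin + (seq_len(n_new) - 1) * target)
}

#' @describeIn preprocessing Resample a volume to cubic voxels with trilinear
#'   interpolation. The output grid starts at the input origin and covers the
#'   input voxel-centre extent; an input already on the target cubic grid is
#'   returned value-identical.
#' @param vol an [image_volume()].
#' @param target_spacing_mm target cubic voxel edge in mm.
#' @return An `image_volume` / `roi_mask` on the target grid.
#' @export
resample_volume <- function(vol, target_spacing_mm = 5.5) {
  stopifnot(inherits(vol, "image_volume"))
  if (target_spacing_mm <= 0) stop_petrad("target spacing must be positive")
  n <- dim(vol$values); sp <- vol$spacing_mm; or <- vol$origin_mm
  if (all(abs(sp - target_spacing_mm) < 1e-9)) return(vol)
  ax <- lapply(1:3, function(a) resampled_axis(n[a], sp[a], or[a], target_spacing_mm))
  out <- interp_trilinear_grid(vol$values, sp, or,
                               ax[[1]]$coords, ax[[2]]$coords, ax[[3]]$coords)
  image_volume(out, rep(target_spacing_mm, 3), or, vol$modality)
}

#' @describeIn preprocessing Resample a binary mask: the 0/1 indicator is
#'   trilinearly interpolated and re-binarized at 0.5 (volume-preserving in
#'   expectation). An empty result carries attribute `empty = TRUE`.
#' @param mask a [roi_mask()].
#' @param method `"linear"` (default) or `"nearest"`.
#' @export
resample_mask <- function(mask, target_spacing_mm = 5.5,
                          method = c("linear", "nearest")) {
  stopifnot(inherits(mask, "roi_mask"))
  method <- match.arg(method)
  vol <- image_volume(mask$values * 1.0, mask$spacing_mm, mask$origin_mm, "SUV")
  res <- resample_volume(vol, target_spacing_mm)
  bin <- if (method == "linear") res$values >= 0.5 else res$values > 0.5
  out <- roi_mask(bin, res$spacing_mm, res$origin_mm)
  if (!any(bin)) {
    warning("mask is empty after resampling", call. = FALSE)
    attr(out, "empty") <- TRUE
  }
  out
}

#' @describeIn preprocessing Intersect the ROI with the CT Hounsfield window
#'   `[hu_min, hu_max]` (both bounds inclusive); removes bone and lung voxels.
#' @param ct an HU `image_volume` on the same grid as `mask`.
#' @param hu_min,hu_max inclusive HU window.
#' @export
apply_hu_exclusion <- function(mask, ct, hu_min = -300, hu_max = 200) {
  stopifnot(inherits(mask, "roi_mask"), inherits(ct, "image_volume"))
  if (!same_geometry(mask, ct)) stop_petrad("mask and CT geometry mismatch")
  keep <- mask$values & ct$values >= hu_min & ct$values <= hu_max
  roi_mask(keep, mask$spacing_mm, mask$origin_mm)
}

#' @describeIn preprocessing Minimum-size gate: `TRUE` iff the (post-exclusion,
#'   post-resampling) ROI holds at least `min_voxels` voxels.
#' @param min_voxels inclusion threshold in voxels.
#' @export
size_gate <- function(mask, min_voxels = 72) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$values) >= min_voxels
}

#' @describeIn preprocessing Fixed-bin-size discretization of ROI intensities:
#'   bin index `floor(value / bin_size) + 1`, bins anchored at 0 with
#'   left-closed intervals. SUV is non-negative by construction; negative
#'   values are clamped to bin 1 with a warning. For wavelet subbands use
#'   `anchor = "min"`, which shifts values by the ROI minimum first.
#' @param bin_size bin width in intensity units (0.25 SUV default).
#' @param anchor `"zero"` (SUV convention) or `"min"` (wavelet subbands).
#' @return `discretize()`: a `discretized_roi` with `values` (integer bin
#'   indices, `NA` outside the ROI), `n_bins` and `bin_size`.
#' @export
discretize <- function(vol, mask, bin_size = 0.25, anchor = c("zero", "min")) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "roi_mask"))
  anchor <- match.arg(anchor)
  if (!same_geometry(vol, mask)) stop_petrad("volume and mask geometry mismatch")
  if (!any(mask$values)) stop_petrad("cannot discretize an empty ROI")
  v <- vol$values
  if (anchor == "min") v <- v - min(v[mask$values])
  if (anchor == "zero" && any(v[mask$values] < 0)) {
    warning("negative intensities inside ROI clamped to bin 1", call. = FALSE)
  }
  idx <- array(NA_integer_, dim = dim(v))
  idx[mask$values] <- pmax(floor(v[mask$values] / bin_size), 0) + 1L
  structure(
    list(values = idx, n_bins = max(idx, na.rm = TRUE), bin_size = bin_size,
         spacing_mm = vol$spacing_mm),
    class = "discretized_roi"
  )
}

#' Run the full preprocessing chain on a PET/CT/mask triplet
#'
#' Resamples all three inputs to the target cubic grid, applies the HU
#' exclusion, and evaluates the size gate. Discretization happens later,
#' per image (SUV or wavelet subband), during feature extraction.
#'
#' @inheritParams preprocessing
#' @param pet,ct,mask native-resolution inputs on a common grid.
#' @param target_spacing_mm,hu_min,hu_max,min_voxels preprocessing parameters.
#' @return A list `pet`, `ct`, `mask` (resampled; mask post-exclusion),
#'   `included` (size-gate verdict) and `n_voxels`.
#' @export
preprocess_case <- function(pet, ct, mask, target_spacing_mm = 5.5,
                            hu_min = -300, hu_max = 200, min_voxels = 72) {
  pet_r <- resample_volume(pet, target_spacing_mm)
  ct_r <- resample_volume(ct, target_spacing_mm)
  mask_r <- suppressWarnings(resample_mask(mask, target_spacing_mm))
  mask_f <- apply_hu_exclusion(mask_r, ct_r, hu_min, hu_max)
  n_vox <- sum(mask_f$values)
  list(pet = pet_r, ct = ct_r, mask = mask_f,
       included = size_gate(mask_f, min_voxels), n_voxels = n_vox)
}
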