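#' Specification of a synthetic PET/CT tumour phantom
#'
#' A phantom is an ellipsoidal tumour with spatially correlated uptake
#' heterogeneity placed on a low-uptake, lung-like background. The companion
#' CT assigns lung HU outside the tumour, soft-tissue HU inside, and a
#' bone-like spherical insert straddling the tumour boundary so that the HU
#' exclusion rule is exercised.
#'
#' The `"default"` preset produces a tumour whose ROI still holds at least 72
#' voxels after resampling to 5.5 mm cubic voxels; the `"small"` preset falls
#' below that gate.
#'
#' @param seed integer seed controlling the uptake heterogeneity field.
#' @param grid_shape integer length 3, voxels per axis.
#' @param voxel_spacing_mm numeric length 3, native voxel spacing.
#' @param tumour_centre physical tumour centre in mm (defaults to grid centre).
#' @param tumour_radii_mm ellipsoid semi-axes in mm.
#' @param suv_background background SUV (>= 0).
#' @param suv_tumour_mean mean tumour SUV (> 0).
#' @param heterogeneity_scale_mm correlation length of the uptake field.
#' @param heterogeneity_amplitude SUV standard deviation of the uptake field.
#' @param preset `"default"` or `"small"`; presets override `tumour_radii_mm`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(seed = 1L,
                         grid_shape = c(36L, 36L, 36L),
                         voxel_spacing_mm = c(3, 3, 3),
                         tumour_centre = NULL,
                         tumour_radii_mm = c(20, 18, 16),
                         suv_background = 0.4,
                         suv_tumour_mean = 6,
                         heterogeneity_scale_mm = 9,
                         heterogeneity_amplitude = 1.5,
                         preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("default", "small"))
    tumour_radii_mm <- switch(preset, default = c(20, 18, 16), small = c(10, 9, 8))
  }
  if (length(grid_shape) != 3 || any(grid_shape < 4)) {
    stop_petrad("`grid_shape` must be 3 integers >= 4")
  }
  if (any(voxel_spacing_mm <= 0)) stop_petrad("voxel spacing must be positive")
  if (is.null(tumour_centre)) {
    tumour_centre <- (grid_shape - 1) / 2 * voxel_spacing_mm
  }
  if (any(tumour_radii_mm <= 0)) stop_petrad("tumour radii must be positive")
  if (suv_background < 0 || suv_tumour_mean <= 0 || heterogeneity_amplitude < 0 ||
      heterogeneity_scale_mm <= 0) {
    stop_petrad("SUV and heterogeneity parameters out of range")
  }
  extent_lo <- -voxel_spacing_mm / 2
  extent_hi <- (grid_shape - 0.5) * voxel_spacing_mm
  if (any(tumour_centre - tumour_radii_mm < extent_lo) ||
      any(tumour_centre + tumour_radii_mm > extent_hi)) {
    stop_petrad("tumour does not fit inside the grid: centre ",
                paste(round(tumour_centre, 1), collapse = ", "),
                " mm with radii ", paste(tumour_radii_mm, collapse = ", "), " mm")
  }
  structure(
    list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
         voxel_spacing_mm = as.numeric(voxel_spacing_mm),
         tumour_centre = as.numeric(tumour_centre),
         tumour_radii_mm = as.numeric(tumour_radii_mm),
         suv_background = suv_background, suv_tumour_mean = suv_tumour_mean,
         heterogeneity_scale_mm = heterogeneity_scale_mm,
         heterogeneity_amplitude = heterogeneity_amplitude),
    class = "phantom_spec"
  )
}

# Squared normalized ellipsoid distance of every voxel centre; <= 1 is inside.
ellipsoid_field <- function(spec) {
  gs <- spec$grid_shape; sp <- spec$voxel_spacing_mm
  cx <- axis_coords(gs[1], sp[1], 0); cy <- axis_coords(gs[2], sp[2], 0)
  cz <- axis_coords(gs[3], sp[3], 0)
  dx2 <- ((cx - spec$tumour_centre[1]) / spec$tumour_radii_mm[1])^2
  dy2 <- ((cy - spec$tumour_centre[2]) / spec$tumour_radii_mm[2])^2
  dz2 <- ((cz - spec$tumour_centre[3]) / spec$tumour_radii_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Generate a synthetic PET/CT phantom
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `pet`, `ct` ([image_volume()]), `mask`
#'   ([roi_mask()]) and `truth` (analytic tumour volume, voxelized volume,
#'   the true mask, and generator parameters).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; sp <- spec$voxel_spacing_mm
  inside <- ellipsoid_field(spec) <= 1

  pet <- array(spec$suv_background, dim = gs)
  if (spec$heterogeneity_amplitude > 0) {
    f <- gaussian_random_field(gs, sp, spec$heterogeneity_scale_mm, spec$seed)
    tumour_vals <- spec$suv_tumour_mean + spec$heterogeneity_amplitude * f[inside]
  } else {
    tumour_vals <- rep(spec$suv_tumour_mean, sum(inside))
  }
  pet[inside] <- pmax(tumour_vals, 0)

  # CT: lung background, soft tissue tumour, bone sphere on the +x boundary.
  ct <- array(-700, dim = gs)
  ct[inside] <- 40
  bone_centre <- spec$tumour_centre + c(spec$tumour_radii_mm[1], 0, 0)
  bone_r <- max(6, 2 * max(sp))
  cx <- axis_coords(gs[1], sp[1], 0); cy <- axis_coords(gs[2], sp[2], 0)
  cz <- axis_coords(gs[3], sp[3], 0)
  bone <- outer(outer((cx - bone_centre[1])^2, (cy - bone_centre[2])^2, `+`),
                (cz - bone_centre[3])^2, `+`) <= bone_r^2
  ct[bone] <- 700

  truth <- list(
    volume_mm3_analytic = 4 / 3 * pi * prod(spec$tumour_radii_mm),
    volume_mm3_voxelized = sum(inside) * prod(sp),
    n_voxels_native = sum(inside),
    mask = inside,
    spec = spec
  )
  list(
    pet = image_volume(pet, sp, modality = "SUV"),
    ct = image_volume(ct, sp, modality = "HU"),
    mask = roi_mask(inside, sp),
    truth = truth
  )
}
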