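#' Image volumes and ROI masks
#'
#' `image_volume()` wraps a 3D scalar grid (SUV, HU or wavelet coefficients)
#' with its voxel spacing and origin; `roi_mask()` wraps a binary grid sharing
#' the geometry of its companion volume. The origin is the physical position
#' (mm) of the centre of voxel `[1, 1, 1]`.
#'
#' @param values 3D numeric (or logical, for masks) array.
#' @param spacing_mm voxel spacing in mm, length 3, strictly positive.
#' @param origin_mm physical position of the first voxel centre, length 3.
#' @param modality one of `"SUV"`, `"HU"`, `"WAVELET"`.
#' @return An object of class `image_volume` or `roi_mask`.
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                         modality = c("SUV", "HU", "WAVELET")) {
  modality <- match.arg(modality)
  values <- as.array(values)
  if (length(dim(values)) != 3) stop_petrad("`values` must be a 3D array")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop_petrad("`spacing_mm` must be 3 strictly positive values")
  }
  if (any(!is.finite(values))) stop_petrad("volume contains non-finite values")
  structure(
    list(values = values, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm), modality = modality),
    class = "image_volume"
  )
}

#' @rdname image_volume
#' @export
roi_mask <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop_petrad("`values` must be a 3D array")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop_petrad("`spacing_mm` must be 3 strictly positive values")
  }
  storage.mode(values) <- "logical"
  structure(
    list(values = values, spacing_mm = as.numeric(spacing_mm),
         origin_mm = as.numeric(origin_mm)),
    class = "roi_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume [%s]> %s, spacing %s mm, range [%.3g, %.3g]\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s, spacing %s mm, %d voxels in ROI\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' @export
dim.roi_mask <- function(x) dim(x$values)

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

# Physical coordinates (mm) of voxel centres along one axis.
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

#' Read or write a volume as NIfTI
#'
#' Thin wrappers over RNifti keeping spacing in the header. Masks are stored
#' as 0/1 integer volumes.
#'
#' @param vol an `image_volume` or `roi_mask`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param modality modality tag to assign on read.
#' @return `write_nifti_volume()` returns `path` invisibly;
#'   `read_nifti_volume()` returns an `image_volume`, `read_nifti_mask()` a
#'   `roi_mask`.
#' @export
write_nifti_volume <- function(vol, path) {
  arr <- vol$values
  if (is.logical(arr)) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path, modality = "SUV") {
  img <- RNifti::readNifti(path)
  image_volume(as.array(img), RNifti::pixdim(img)[1:3], modality = modality)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_mask <- function(path) {
  img <- RNifti::readNifti(path)
  roi_mask(as.array(img) > 0.5, RNifti::pixdim(img)[1:3])
}
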