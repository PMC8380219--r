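#' Extract the full 1404-feature radiomic signature
#'
#' Runs the complete chain on a co-registered PET/CT/mask triplet: resampling
#' to the cubic grid, HU exclusion, size gating, fixed-bin-size
#' discretization, then 18 shape + 17 intensity + 137 texture features on the
#' SUV ROI and 17 intensity + 137 texture features on each of the 8
#' undecimated Haar subbands — 1404 features in a fixed, deterministic order.
#'
#' @param pet,ct,mask native-grid inputs ([image_volume()] / [roi_mask()]).
#' @param config extraction parameters from [extract_config()].
#' @return A named numeric vector of length 1404 (the feature vector). If the
#'   ROI fails the size gate an `excluded_case` record (with the reason and
#'   the voxel count) is returned instead; `extract_all()` never errors on
#'   small tumours.
#' @export
extract_all <- function(pet, ct, mask, config = extract_config()) {
  pc <- preprocess_case(pet, ct, mask,
                        target_spacing_mm = config$target_spacing_mm,
                        hu_min = config$hu_range[1], hu_max = config$hu_range[2],
                        min_voxels = config$min_voxels)
  if (!pc$included) {
    return(structure(list(reason = sprintf("excluded: %d voxels < %d",
                                           pc$n_voxels, config$min_voxels),
                          n_voxels = pc$n_voxels),
                     class = "excluded_case"))
  }
  extract_from_preprocessed(pc$pet, pc$mask, config)
}

# Feature computation on an already preprocessed (resampled, gated) case.
extract_from_preprocessed <- function(pet_r, mask_f, config = extract_config()) {
  dsuv <- discretize(pet_r, mask_f, config$bin_size_suv, anchor = "zero")
  fv <- c(
    shape_features(mask_f),
    intensity_features(pet_r$values[mask_f$values], config$bin_size_suv,
                       bin_idx = dsuv$values[mask_f$values],
                       prefix = "intensity/suv/"),
    texture_features(dsuv, prefix = "texture/")
  )
  subbands <- wavelet_decompose(pet_r, normalization = "unit")
  for (lab in names(subbands)) {
    sb <- subbands[[lab]]
    dsb <- discretize(sb, mask_f, config$bin_size_suv, anchor = "min")
    fv <- c(
      fv,
      intensity_features(sb$values[mask_f$values], config$bin_size_suv,
                         bin_idx = dsb$values[mask_f$values],
                         prefix = sprintf("wavelet/%s/intensity_", lab)),
      texture_features(dsb, prefix = sprintf("wavelet/%s/", lab))
    )
  }
  fv
}

#' @describeIn extract_all Extraction parameters: target cubic spacing (mm),
#'   SUV bin size, inclusive HU window and the minimum ROI voxel count.
#' @param target_spacing_mm,bin_size_suv,hu_range,min_voxels see Description.
#' @export
extract_config <- function(target_spacing_mm = 5.5, bin_size_suv = 0.25,
                           hu_range = c(-300, 200), min_voxels = 72) {
  list(target_spacing_mm = target_spacing_mm, bin_size_suv = bin_size_suv,
       hu_range = hu_range, min_voxels = min_voxels)
}

#' Feature-family membership
#'
#' Maps feature names to the four families of the signature (shape,
#' intensity, texture, wavelet).
#'
#' @param feature_names character vector of feature names.
#' @return Character vector of family labels.
#' @export
feature_family <- function(feature_names) {
  fam <- sub("/.*$", "", feature_names)
  fam[!fam %in% c("shape", "intensity", "texture", "wavelet")] <- NA_character_
  fam
}

#' Extract features for a list of cases into a feature table
#'
#' @param cases list of lists with elements `pet`, `ct`, `mask` (and
#'   optionally `patient_id`).
#' @param config extraction parameters from [extract_config()].
#' @return A tibble: `patient_id` plus one column per feature; excluded cases
#'   (size gate) are dropped and recorded in attribute `excluded`.
#' @export
extract_cohort_features <- function(cases, config = extract_config()) {
  rows <- list()
  excluded <- character(0)
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    pid <- cs$patient_id %||% sprintf("P%03d", k)
    fv <- extract_all(cs$pet, cs$ct, cs$mask, config)
    if (inherits(fv, "excluded_case")) {
      excluded[pid] <- fv$reason
      next
    }
    rows[[pid]] <- fv
  }
  tbl <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::as_tibble(as.list(r))
  }))
  tbl <- dplyr::bind_cols(tibble::tibble(patient_id = names(rows)), tbl)
  attr(tbl, "excluded") <- excluded
  tbl
}

#' Write a feature table with a provenance sidecar
#'
#' Writes the table as CSV and a JSON sidecar carrying the extraction
#' configuration and feature roster so a run can be reproduced.
#'
#' @param features feature tibble from [extract_cohort_features()].
#' @param path output CSV path; the sidecar is `<path>.json`.
#' @param config extraction parameters.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, config = extract_config()) {
  utils::write.csv(features, path, row.names = FALSE)
  sidecar <- list(
    config = config,
    n_features = sum(names(features) != "patient_id"),
    roster = setdiff(names(features), "patient_id"),
    package_version = as.character(utils::packageVersion("petrad"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
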