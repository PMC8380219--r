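#' Feature-robustness studies
#'
#' A robustness study compares the same patients' feature vectors across
#' perturbation conditions (conditions play the role of raters). Per-feature
#' ICCs are computed with the study's ICC form, a feature is called stable
#' when its ICC exceeds 0.9 (strict), and the stable sets of the three
#' studies are intersected into the final robust set.
#'
#' Default study-to-form mapping: delineation uses ICC(1,1) over the three
#' contouring methods, attenuation ICC(3,1) over its two conditions, motion
#' ICC(3,k) (average measures over the gated/ungated pair). The mapping is an
#' argument, not a constant.
#'
#' @param name study label: `"delineation"`, `"attenuation"` or `"motion"`.
#' @param tables list (one per condition) of feature tibbles sharing a
#'   `patient_id` column and identical feature columns.
#' @param icc_form ICC form for the study (see [icc()]).
#' @return `robustness_study()`: a `robustness_study` object.
#' @export
robustness_study <- function(name, tables,
                             icc_form = default_icc_mapping()[[name]]) {
  name <- match.arg(name, c("delineation", "attenuation", "motion"))
  if (length(tables) < 2) stop_petrad("a robustness study needs >= 2 conditions")
  ids <- lapply(tables, function(t) sort(t$patient_id))
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    stop_petrad("condition tables must share the same patient set")
  }
  feats <- lapply(tables, function(t) setdiff(names(t), "patient_id"))
  if (!all(vapply(feats[-1], identical, logical(1), feats[[1]]))) {
    stop_petrad("condition tables must share the same feature set")
  }
  structure(list(name = name, tables = tables, icc_form = icc_form),
            class = "robustness_study")
}

#' @describeIn robustness_study The default study-to-ICC-form mapping.
#' @export
default_icc_mapping <- function() {
  list(delineation = "ICC_1_1", attenuation = "ICC_3_1", motion = "ICC_3_k")
}

#' @describeIn robustness_study Per-feature ICCs and stability flags for one
#'   study, plus the per-family percent-stable summary in attribute
#'   `family_summary`.
#' @param study a `robustness_study`.
#' @param threshold stability threshold (strict inequality).
#' @return `run_study()`: tibble with columns `feature`, `family`, `icc`,
#'   `stable`.
#' @export
run_study <- function(study, threshold = 0.9) {
  stopifnot(inherits(study, "robustness_study"))
  tabs <- lapply(study$tables, function(t) t[order(t$patient_id), , drop = FALSE])
  feats <- setdiff(names(tabs[[1]]), "patient_id")
  iccs <- vapply(feats, function(f) {
    m <- vapply(tabs, function(t) t[[f]], numeric(nrow(tabs[[1]])))
    icc(m, study$icc_form, warn = FALSE)
  }, numeric(1))
  res <- tibble::tibble(
    feature = feats,
    family = feature_family(feats),
    icc = unname(iccs),
    stable = unname(iccs) > threshold
  )
  attr(res, "family_summary") <- family_stability(res)
  attr(res, "study") <- study$name
  res
}

#' @describeIn robustness_study Percent of stable features per family
#'   (shape / intensity / texture / wavelet), as plotted in stability bar
#'   charts.
#' @param result a `run_study()` tibble.
#' @export
family_stability <- function(result) {
  result |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n = dplyr::n(),
                     n_stable = sum(.data$stable),
                     pct_stable = 100 * mean(.data$stable),
                     .groups = "drop")
}

#' Intersect the stable sets of the three robustness studies
#'
#' @param results named list of three `run_study()` tibbles (delineation,
#'   attenuation, motion).
#' @return A list with `robust_features` (stable in all three studies),
#'   `fraction_robust`, and `venn` — a tibble of the 7 exclusive region
#'   counts, overall and per feature family.
#' @export
intersect_stable <- function(results) {
  if (length(results) != 3) stop_petrad("need exactly three study results")
  sets <- lapply(results, function(r) r$feature[r$stable])
  all_feats <- results[[1]]$feature
  in1 <- all_feats %in% sets[[1]]
  in2 <- all_feats %in% sets[[2]]
  in3 <- all_feats %in% sets[[3]]
  nm <- names(results) %||% c("study1", "study2", "study3")
  region <- dplyr::case_when(
    in1 & in2 & in3 ~ "all_three",
    in1 & in2 ~ paste(nm[1], nm[2], sep = "+"),
    in1 & in3 ~ paste(nm[1], nm[3], sep = "+"),
    in2 & in3 ~ paste(nm[2], nm[3], sep = "+"),
    in1 ~ paste0(nm[1], "_only"),
    in2 ~ paste0(nm[2], "_only"),
    in3 ~ paste0(nm[3], "_only"),
    TRUE ~ "none"
  )
  venn <- tibble::tibble(feature = all_feats,
                         family = feature_family(all_feats),
                         region = region) |>
    dplyr::filter(.data$region != "none") |>
    dplyr::count(.data$region, .data$family, name = "n")
  robust <- all_feats[in1 & in2 & in3]
  list(robust_features = robust,
       fraction_robust = length(robust) / length(all_feats),
       venn = venn)
}

#' Simulate an image-based robustness study
#'
#' Generates `n_patients` phantoms (randomized around a template), applies
#' the study's perturbation pairing, extracts the full feature signature per
#' condition, and returns a ready-to-run [robustness_study()]:
#' * delineation — three contouring variants of the same scan;
#' * attenuation — original vs. a scanner-change surrogate (multiplicative
#'   bias field plus a mild isotropic point-spread-function difference,
#'   since the paired acquisitions come from different scanners);
#' * motion — original ("gated") vs. anisotropic blur ("free-breathing").
#'
#' @param name study label.
#' @param n_patients number of phantoms.
#' @param seed master seed.
#' @param template a [phantom_spec()] used as randomization template.
#' @param bias_strength attenuation bias amplitude.
#' @param psf_fwhm_mm isotropic resolution difference (mm FWHM) between the
#'   paired attenuation-study scanners; 0 disables it.
#' @param blur_fwhm_mm motion blur FWHM (mm, per axis).
#' @param threshold_pct delineation threshold fraction of SUVmax.
#' @param config extraction parameters.
#' @return A `robustness_study`.
#' @export
simulate_robustness_study <- function(name, n_patients = 8, seed = 1L,
                                      template = phantom_spec(),
                                      bias_strength = 0.2,
                                      psf_fwhm_mm = 4,
                                      blur_fwhm_mm = c(4, 4, 12),
                                      threshold_pct = 0.35,
                                      config = extract_config()) {
  name <- match.arg(name, c("delineation", "attenuation", "motion"))
  conds <- switch(name,
                  delineation = c("manual", "threshold", "gradient"),
                  attenuation = c("ct_based", "mr_based"),
                  motion = c("gated", "free_breathing"))
  rows <- stats::setNames(vector("list", length(conds)), conds)
  for (p in seq_len(n_patients)) {
    pseed <- derive_seed(seed, paste0(name, "_patient_", p))
    spec <- randomize_phantom_spec(template, pseed)
    ph <- generate_phantom(spec)
    imgs <- switch(
      name,
      delineation = {
        vars <- delineation_variants(ph$pet, ph$mask, threshold_pct,
                                     seed = derive_seed(pseed, "delin"))
        lapply(vars, function(m) list(pet = ph$pet, ct = ph$ct, mask = m))
      },
      attenuation = list(
        ct_based = list(pet = ph$pet, ct = ph$ct, mask = ph$mask),
        mr_based = list(
          pet = motion_variant(
            attenuation_variant(ph$pet, bias_strength,
                                seed = derive_seed(pseed, "bias")),
            rep(psf_fwhm_mm, 3)),
          ct = ph$ct, mask = ph$mask)
      ),
      motion = list(
        gated = list(pet = ph$pet, ct = ph$ct, mask = ph$mask),
        free_breathing = list(pet = motion_variant(ph$pet, blur_fwhm_mm),
                              ct = ph$ct, mask = ph$mask)
      )
    )
    names(imgs) <- conds
    for (cn in conds) {
      fv <- extract_all(imgs[[cn]]$pet, imgs[[cn]]$ct, imgs[[cn]]$mask, config)
      if (inherits(fv, "excluded_case")) {
        stop_petrad("phantom failed the size gate in study ", name, ": ", fv$reason)
      }
      rows[[cn]][[sprintf("P%03d", p)]] <- fv
    }
  }
  tables <- lapply(rows, function(r) {
    dplyr::bind_cols(tibble::tibble(patient_id = names(r)),
                     dplyr::bind_rows(lapply(r, function(x) tibble::as_tibble(as.list(x)))))
  })
  robustness_study(name, tables)
}

#' Simulate feature-level robustness studies
#'
#' Builds the three perturbation studies directly on a feature table:
#' each condition table is the original plus condition-specific noise whose
#' magnitude depends on whether a feature is designated non-robust
#' (perturbation-sensitive) or robust. Used to construct modelling scenarios
#' with a known robust set, e.g. one where every outcome-informative feature
#' is made perturbation-sensitive.
#'
#' @param features feature tibble (`patient_id` + feature columns).
#' @param nonrobust_features names of features to make perturbation-sensitive.
#' @param seed master seed.
#' @param sd_nonrobust,sd_robust condition-noise magnitude relative to each
#'   feature's between-patient standard deviation.
#' @return Named list of three [robustness_study()] objects.
#' @export
simulate_feature_robustness <- function(features, nonrobust_features,
                                        seed = 1L, sd_nonrobust = 1.5,
                                        sd_robust = 0.02) {
  feats <- setdiff(names(features), "patient_id")
  bad <- setdiff(nonrobust_features, feats)
  if (length(bad)) stop_petrad("unknown feature(s): ", paste(bad, collapse = ", "))
  n <- nrow(features)
  rel <- stats::setNames(rep(sd_robust, length(feats)), feats)
  rel[nonrobust_features] <- sd_nonrobust
  sds <- vapply(feats, function(f) stats::sd(features[[f]]), numeric(1))
  sds[sds == 0] <- 1
  make_condition <- function(study, cond) {
    noise_seed <- derive_seed(seed, paste0(study, "_", cond))
    noise <- with_seed(noise_seed,
                       matrix(stats::rnorm(n * length(feats)), n, length(feats)))
    tab <- features
    for (k in seq_along(feats)) {
      tab[[feats[k]]] <- features[[feats[k]]] + rel[k] * sds[k] * noise[, k]
    }
    tab
  }
  studies <- list(
    delineation = lapply(c("manual", "threshold", "gradient"),
                         function(cn) make_condition("delineation", cn)),
    attenuation = lapply(c("ct_based", "mr_based"),
                         function(cn) make_condition("attenuation", cn)),
    motion = lapply(c("gated", "free_breathing"),
                    function(cn) make_condition("motion", cn))
  )
  purrr::imap(studies, function(tabs, nm) robustness_study(nm, tabs))
}

# Jitter the template's tumour geometry and uptake so patients differ.
randomize_phantom_spec <- function(template, seed) {
  with_seed(seed, {
    radii <- template$tumour_radii_mm * stats::runif(3, 0.9, 1.15)
    suv <- template$suv_tumour_mean * stats::runif(1, 0.8, 1.25)
    het <- template$heterogeneity_amplitude * stats::runif(1, 0.7, 1.3)
    phantom_spec(seed = derive_seed(seed, "field"),
                 grid_shape = template$grid_shape,
                 voxel_spacing_mm = template$voxel_spacing_mm,
                 tumour_radii_mm = radii,
                 suv_background = template$suv_background,
                 suv_tumour_mean = suv,
                 heterogeneity_scale_mm = template$heterogeneity_scale_mm,
                 heterogeneity_amplitude = het)
  })
}
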