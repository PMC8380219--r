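#' Reproducible end-to-end study runs
#'
#' `run_config()` assembles a single configuration (one master seed, all
#' stage parameters) and `run_radiomics_study()` executes the full chain:
#' simulate the three robustness studies, derive the robust feature set,
#' simulate training and validation cohorts, and fit the prognostic models
#' for every requested endpoint twice (all features vs. robust-only). Every
#' output file gets a JSON sidecar with the serialized configuration and its
#' hash; two runs with the same configuration produce identical outputs.
#'
#' @param seed master seed; all stage seeds derive from it deterministically.
#' @param n_robustness_patients phantoms per robustness study.
#' @param n_train,n_valid cohort sizes for the modelling stage
#'   (feature-level cohorts).
#' @param n_features,target_auc feature-level cohort design.
#' @param endpoints character vector like `c("efs_12", "os_24")`; horizons
#'   must be 12, 18 or 24.
#' @param icc_mapping study-to-ICC-form mapping.
#' @param lambda model-selection trade-off weight.
#' @param rho G-rho test exponent.
#' @param horn_reps Horn parallel-analysis replicates.
#' @param cv_folds cross-validation folds.
#' @param extraction extraction parameters ([extract_config()]).
#' @return `run_config()`: a named list.
#' @export
run_config <- function(seed = 1L, n_robustness_patients = 8,
                       n_train = 300, n_valid = 150, n_features = 25,
                       target_auc = 0.75,
                       endpoints = c("efs_12", "efs_24", "os_12", "os_24"),
                       icc_mapping = default_icc_mapping(),
                       lambda = 0.5, rho = 0, horn_reps = 200, cv_folds = 5,
                       extraction = extract_config()) {
  parsed <- strsplit(endpoints, "_", fixed = TRUE)
  ok <- vapply(parsed, function(p) {
    length(p) == 2 && p[1] %in% c("efs", "os") && p[2] %in% c("12", "18", "24")
  }, logical(1))
  if (!all(ok)) {
    stop_petrad("unknown endpoint(s): ", paste(endpoints[!ok], collapse = ", "),
                "; use <efs|os>_<12|18|24>")
  }
  list(seed = as.integer(seed), n_robustness_patients = n_robustness_patients,
       n_train = n_train, n_valid = n_valid, n_features = n_features,
       target_auc = target_auc, endpoints = endpoints,
       icc_mapping = icc_mapping, lambda = lambda, rho = rho,
       horn_reps = horn_reps, cv_folds = cv_folds, extraction = extraction)
}

#' @describeIn run_config Execute the configured study end to end.
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param include_robustness run the (slower) image-based robustness stage.
#' @return `run_radiomics_study()`: a list with `robustness` (per-study ICC
#'   tibbles + intersection), `models` (per endpoint x feature-set tibble),
#'   `selection` (ranked models) and `config`.
#' @export
run_radiomics_study <- function(config = run_config(), out_dir = NULL,
                                include_robustness = TRUE) {
  results <- list(config = config)

  if (include_robustness) {
    studies <- lapply(c("delineation", "attenuation", "motion"), function(nm) {
      st <- simulate_robustness_study(
        nm, n_patients = config$n_robustness_patients,
        seed = derive_seed(config$seed, paste0("rob_", nm)),
        config = config$extraction)
      st$icc_form <- config$icc_mapping[[nm]]
      run_study(st)
    })
    names(studies) <- c("delineation", "attenuation", "motion")
    results$robustness <- list(studies = studies,
                               intersection = intersect_stable(studies))
  }

  cohort_tr <- simulate_feature_cohort(
    n_patients = config$n_train, n_features = config$n_features,
    target_auc = config$target_auc, seed = derive_seed(config$seed, "train"))
  cohort_va <- simulate_feature_cohort(
    n_patients = config$n_valid, n_features = config$n_features,
    target_auc = config$target_auc, seed = derive_seed(config$seed, "valid"))

  # Robust set for the modelling features: feature-level perturbation
  # studies on the training cohort. The default scenario makes the
  # outcome-informative features perturbation-sensitive.
  fstudies <- simulate_feature_robustness(
    cohort_tr$features, cohort_tr$truth$informative_features,
    seed = derive_seed(config$seed, "feature_robustness"))
  fresults <- purrr::imap(fstudies, function(st, nm) {
    st$icc_form <- config$icc_mapping[[nm]]
    run_study(st)
  })
  robust_cols <- intersect_stable(fresults)$robust_features
  results$feature_robustness <- list(studies = fresults,
                                     robust_features = robust_cols)

  model_rows <- list()
  for (ep in config$endpoints) {
    parts <- strsplit(ep, "_")[[1]]
    outc <- parts[1]; hor <- as.numeric(parts[2])
    lab_tr <- binarize_outcomes(cohort_tr$outcomes, outc, hor)
    lab_va <- binarize_outcomes(cohort_va$outcomes, outc, hor)
    ftr <- cohort_tr$features[match(lab_tr$patient_id, cohort_tr$features$patient_id), ]
    fva <- cohort_va$features[match(lab_va$patient_id, cohort_va$features$patient_id), ]
    for (fs in c("all", "robust")) {
      cols <- setdiff(names(ftr), "patient_id")
      if (fs == "robust") cols <- intersect(cols, robust_cols)
      if (fs == "robust" && length(cols) < 2) {
        model_rows[[paste(ep, fs, sep = "_")]] <- tibble::tibble(
          endpoint_id = paste(ep, fs, sep = "_"), outcome = outc,
          horizon_months = hor, feature_set = fs, n_selected = 0L,
          cv_auc_mean = 0.5, cv_auc_range = 0, validation_auc = 0.5,
          validation_ci_lo = NA_real_, validation_ci_hi = NA_real_,
          model = list(NULL))
        next
      }
      ep_spec <- list(outcome = outc, horizon_months = hor, feature_set = fs)
      seed_ep <- derive_seed(config$seed, paste0("model_", ep, "_", fs))
      model <- fit_prognostic_pipeline(ftr[cols], lab_tr$label, ep_spec,
                                       horn_reps = config$horn_reps,
                                       seed = seed_ep)
      cv <- cross_validate(ftr[cols], lab_tr$label, k = config$cv_folds,
                           seed = seed_ep, horn_reps = config$horn_reps)
      val <- validate_model(model, fva, lab_va$label)
      model_rows[[paste(ep, fs, sep = "_")]] <- tibble::tibble(
        endpoint_id = paste(ep, fs, sep = "_"), outcome = outc,
        horizon_months = hor, feature_set = fs,
        n_selected = length(model$features),
        cv_auc_mean = cv$cv_auc_mean, cv_auc_range = cv$cv_auc_range,
        validation_auc = val$auc,
        validation_ci_lo = val$ci95[1], validation_ci_hi = val$ci95[2],
        model = list(model)
      )
    }
  }
  results$models <- dplyr::bind_rows(model_rows)
  results$selection <- select_best(results$models, lambda = config$lambda)
  results$cohorts <- list(train = cohort_tr, valid = cohort_va)

  if (!is.null(out_dir)) write_study_outputs(results, out_dir)
  results
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

write_study_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sidecar <- list(config = results$config, config_hash = config_hash(results$config),
                  package_version = as.character(utils::packageVersion("petrad")))
  jsonlite::write_json(sidecar, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(results$robustness)) {
    for (nm in names(results$robustness$studies)) {
      utils::write.csv(results$robustness$studies[[nm]],
                       file.path(out_dir, sprintf("icc_%s.csv", nm)),
                       row.names = FALSE)
    }
    venn <- results$robustness$intersection
    jsonlite::write_json(
      list(fraction_robust = venn$fraction_robust,
           n_robust = length(venn$robust_features),
           venn = venn$venn),
      file.path(out_dir, "robust_intersection.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  utils::write.csv(
    dplyr::select(results$models, -"model"),
    file.path(out_dir, "model_metrics.csv"), row.names = FALSE)
  invisible(out_dir)
}
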