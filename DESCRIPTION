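Package: petrad
Title: PET Radiomics Robustness Screening and Prognostic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic test bed for FDG-PET radiomics
    outcome studies in locally advanced lung cancer. Simulates heterogeneous
    tumour phantoms on lung-like CT backgrounds together with delineation,
    attenuation-bias and respiratory-blur perturbations; extracts a 1404-feature
    IBSI-style radiomic signature (shape, intensity, texture matrices and
    undecimated wavelet subbands) from resampled, HU-filtered, fixed-bin-size
    SUV volumes; screens feature robustness with intraclass correlation
    coefficients across perturbation studies; and builds binarized event-free /
    overall survival logistic models with Horn parallel analysis, AUC-driven
    group screening, backward-AIC selection, cross-validation, external
    validation and Kaplan-Meier risk stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    yaml
Config/testthat/edition: 3
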