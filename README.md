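# petrad

PET radiomics studies in locally advanced lung cancer face a double problem:
the 1000+ quantitative features extractable from an FDG-PET tumour volume are
(i) sensitive to how the scan was acquired and contoured, and (ii) candidates
for prognostic models of binarized survival endpoints, where unstable
features silently erode external validity. `petrad` implements the complete
methodology of such a study as a reusable, tested R pipeline, exercised
end-to-end on synthetic phantom and cohort data with known ground truth:

* **Synthetic data** — ellipsoidal tumour phantoms with spatially correlated
  uptake heterogeneity on lung-like CT backgrounds; perturbation pairings for
  three robustness factors (delineation variants, attenuation-style bias,
  respiratory blur); outcome-linked cohorts whose event probability follows a
  logistic model on known features, with a closed-form design AUC.
* **Preprocessing** — resampling to 5.5 mm cubic voxels (trilinear), CT
  Hounsfield-unit exclusion of lung and bone (−300..200, inclusive), a
  72-voxel minimum ROI gate, and fixed-bin-size discretization (0.25 SUV,
  anchored at 0).
* **Features** — a 1404-feature IBSI-style signature: 18 shape, 17 intensity,
  137 texture (GLCM, GLRLM, GLSZM, GLDZM, NGTDM, NGLDM over the 3D
  26-neighbourhood) and 8 × 154 = 1232 features on undecimated Haar wavelet
  subbands (LLL … HHH).
* **Robustness** — per-feature Shrout–Fleiss intraclass correlations,
  ICC(1,1) / ICC(3,1) / ICC(3,k) per study, stability at ICC > 0.9 (strict),
  per-family stability summaries and the three-study intersection with Venn
  region counts.
* **Modelling** — endpoint binarization (EFS/OS at 12/18/24 months), Horn
  parallel analysis, PCA feature grouping, per-group univariable
  Mann–Whitney-AUC screening (Wald p < 0.05), backward-AIC multivariable
  logistic selection, stratified five-fold cross-validation with the whole
  selection pipeline re-run per fold, external validation with DeLong 95%
  CIs, and Kaplan–Meier risk stratification at the training-median predicted
  probability with a Harrington–Fleming G-rho test.

The model at the core: for patient *i* with standardized feature vector
*z<sub>i</sub>*, the probability of an event by the horizon *H* is

> P(event ≤ H) = logistic(β₀ + βᵀ z<sub>i</sub>),

screened so that β ranges only over one max-AUC surrogate per correlated
feature group, and pruned by AIC = 2k − 2ℓ. A feature enters the robust-only
model family only if ICC > 0.9 in **all three** perturbation studies.

## Worked example

```r
library(petrad)

ph <- generate_phantom(phantom_spec(seed = 7))
ph$pet
#> <image_volume [SUV]> 36x36x36, spacing 3x3x3 mm, range [0.4, 7.73]

fv <- extract_all(ph$pet, ph$ct, ph$mask)
length(fv)
#> [1] 1404
round(fv[c("shape/mask/volume_mm3", "intensity/suv/mean",
           "texture/glcm_avg/contrast")], 3)
#>     shape/mask/volume_mm3        intensity/suv/mean texture/glcm_avg/contrast
#>                 23958.000                     5.993                    15.388
```

The volume feature is exact voxel arithmetic (ROI voxels × 5.5³ mm³ after
resampling); the mean is the average SUV over the gated, HU-filtered ROI;
GLCM contrast is the direction-averaged co-occurrence contrast on the
0.25-SUV-binned ROI.

A motion robustness study on six phantoms (gated vs. free-breathing blur):

```r
res <- run_study(simulate_robustness_study("motion", n_patients = 6, seed = 7))
family_stability(res)
#>   family        n n_stable pct_stable
#> 1 intensity    17       15       88.2
#> 2 shape        18       18      100
#> 3 texture     137      107       78.1
#> 4 wavelet    1232      374       30.4
```

Shape is untouched by blur (mask unchanged, ICC = 1) while wavelet features
collapse — the expected ordering for a motion factor.

Prognostic modelling on a synthetic cohort with designed AUC 0.75:

```r
co <- simulate_feature_cohort(n_patients = 200, seed = 7)
lab <- binarize_outcomes(co$outcomes, "efs", 12)
ftr <- co$features[match(lab$patient_id, co$features$patient_id), ]
m <- fit_prognostic_pipeline(ftr, lab$label, seed = 7)
m
#> <prognostic_model> [3 features]
#>   selected: feat_005, feat_012, feat_014
#>   AIC 234.85 | training AUC 0.759 | cutoff 0.539

km <- stratify_km(m, ftr, co$outcomes[match(lab$patient_id,
                                            co$outcomes$patient_id), ], "efs")
km$median_survival
#>   group     median_months
#> 1 high_risk          7.69
#> 2 low_risk          22.0
```

The pipeline selected one feature from each of the three planted correlation
blocks (features 1–7, 8–12, 13–15 are informative), its training AUC is near
the design value, and the median split separates survival by 14 months
(log-rank p = 1.2e-08). `tidy(m)` / `glance(m)` give broom-style summaries;
`autoplot(km)` and `plot_family_stability(res)` draw the standard figures.

`run_radiomics_study(run_config(seed = 1), out_dir = "out")` chains all
stages (robustness studies, robust-set intersection, both model families per
endpoint, model selection) and writes CSV/JSON outputs with a provenance
sidecar. A thin command-line wrapper lives at `inst/cli/radpipe.R`.

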