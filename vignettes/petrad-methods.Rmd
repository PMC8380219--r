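---
title: "Methods: synthetic PET radiomics, robustness screening and prognostic modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic PET radiomics, robustness screening and prognostic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`petrad` implements a complete PET-radiomics outcome-modelling workflow —
feature extraction, ICC-based robustness screening under three perturbation
factors, and prognostic logistic modelling of binarized survival endpoints —
on fully synthetic data with known ground truth. This vignette records the
models, the tunable parameters, the numerical conventions, and the design
choices made where more than one reasonable option existed. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The synthetic data and what it does (not) emulate

**Phantoms.** A tumour is an ellipsoid (default semi-axes 20/18/16 mm) on a
36³ grid of 3 mm voxels. Interior uptake is `suv_tumour_mean` (6 SUV) plus a
Gaussian random field (correlation length 9 mm, amplitude 1.5 SUV as one
standard deviation), clipped at 0; the background is 0.4 SUV. The companion
CT is three-valued: lung (−700 HU) outside, soft tissue (40 HU) inside, and
a 6 mm bone-like sphere (700 HU) straddling the +x tumour boundary so the HU
exclusion rule always has work to do. The default tumour keeps ≥ 72 voxels
after resampling to 5.5 mm; the `"small"` preset (10/9/8 mm) falls below the
gate. Everything is deterministic under the `phantom_spec()` seed.

**Perturbations.**

* *Delineation* (3 conditions): a seeded "manual-like" variant (one-voxel
  dilation of a random half of the boundary — a documented proxy, no human
  is in the loop), a connected-region SUV threshold at 35% of SUVmax grown
  from the hottest voxel (the clinically used band is 27–41%), and a
  "gradient-like" contour at the radius of maximal mean SUV-gradient
  magnitude.
* *Attenuation* (2 conditions): a smooth multiplicative bias field
  (`1 + 0.2·f`, `f` a unit-variance field with 40 mm correlation length,
  normalized to unit mean over the central grid half so average activity is
  preserved) **plus a 4 mm FWHM isotropic blur** in the study simulator.
  The blur is deliberate: the emulated pairing compares two different
  scanners, so a point-spread-function difference is part of the physical
  contrast between conditions. A purely multiplicative smooth bias — at any
  amplitude or correlation length we scanned (0.15–0.35, 10–40 mm) — makes
  the SUV-binned texture matrices the most fragile family and can never
  reproduce the expected "wavelets least stable" ordering; the PSF term
  restores it with a wide margin. `attenuation_variant()` itself remains a
  pure multiplicative bias.
* *Motion* (2 conditions): anisotropic Gaussian blur, FWHM (4, 4, 12) mm
  with the dominant axis mimicking cranio-caudal breathing; the unblurred
  volume plays the gated role. The kernel is mass-preserving up to boundary
  truncation. Real respiratory waveforms, scatter, and reconstruction
  physics are **not** modelled; the blur magnitude is a calibration knob
  chosen once so the family-stability rank ordering matches the expected
  qualitative pattern, and exact stability percentages are not contracts.

**Cohorts.** Two generators share one outcome model: the probability of an
event by the horizon is `plogis(β₀ + βᵀz)` on standardized features; event
times are exponential with the per-patient rate solved from
`P(T ≤ H) = p` (the simplest model satisfying a binarized-endpoint
contract); overall survival adds an exponential post-event tail (mean 9
months); censoring is independent (uniform on `[0, 2H]` for a `censoring_rate`
fraction). The image-based generator (`generate_cohort()`) randomizes
phantom geometry and uptake per patient and ties β to *extracted* features.
The feature-level generator (`simulate_feature_cohort()`) is the workhorse
for modelling studies at n = 300: three latent factors carry the linear
predictor, with distinct block sizes (7/5/3 informative features, loadings
1/0.85/0.7, measurement noise sd 0.3) and 10 independent noise features.
The distinct block sizes matter: with equal blocks the top covariance
eigenvalues are nearly degenerate, principal components rotate freely inside
the signal subspace, and the grouping step occasionally fuses two blocks
while handing a third, noise-dominated component to the screen. Unequal
blocks (eigenvalues ≈ 6.5/4.6/2.8) keep components aligned with blocks.

The *design AUC* is the probability that a case's linear predictor exceeds a
control's, computable in closed form from the simulated predictors
(probability-weighted pairwise comparison); `calibrate_effect_scale()`
inverts the population version of that map by Gauss–Hermite quadrature, so
`target_auc = 0.75` fixes the effect scale deterministically.

Passing tests on these data show the *pipeline machinery* is correct and
identifiable under its own assumptions; they do not show that real FDG-PET
cohorts satisfy those assumptions (Gaussian factors, exponential hazards,
noise-free masks, three-valued CT).

## 2. Preprocessing conventions

Order: resample PET, CT and mask to the common 5.5 mm cubic grid first, then
HU-exclude, then size-gate, then discretize — because the 72-voxel gate is
defined on the resampled grid. Resampling is trilinear; the output grid
starts at the input origin and covers the voxel-centre extent, so an input
already on the target grid passes through value-identical. The mask is
interpolated as a 0/1 field and re-binarized at 0.5 (volume-preserving in
expectation; nearest-neighbour available). The HU window [−300, 200] is
inclusive on both ends. Discretization uses a fixed 0.25 SUV bin anchored at
0 with left-closed intervals — a common anchor is what makes fixed-bin-size
features comparable across patients; negative SUV (impossible by
construction) clamps to bin 1 with a warning. Wavelet coefficients can be
negative, so subbands are discretized after shifting by the ROI minimum,
same bin width.

## 3. The 1404-feature signature

`shape (18) + intensity (17) + texture (137)` on the SUV ROI plus
`intensity (17) + texture (137)` on each of 8 subbands. Only the family
*counts* are normative; the exact rosters are this package's documented
choice (`write_feature_table()` emits the full roster as a sidecar):

* **Texture (137)** = GLCM averaged over the 13 unique 3D directions
  (26 features: 25 standard + the maximal correlation coefficient, the
  documented 137th member) + GLCM merged (25) + GLRLM averaged (16) +
  GLRLM merged (16) + GLSZM (16) + GLDZM (16) + NGTDM (5) + NGLDM (17).
  All matrices use the 26-connected neighbourhood at distance 1; "averaged"
  computes features per direction and averages, "merged" pools matrices
  first. GLDZM distances are city-block steps to the ROI edge (border
  voxels have distance 1); NGLDM uses coarseness 0 and dependence
  `j = k + 1`.
* **Degenerate conventions**: on a single-grey-level ROI, entropy-like GLCM
  features are 0 by construction and correlation, the information
  correlations and the MCC are *defined* as 0 rather than NaN; a constant
  intensity sample has skewness, kurtosis and coefficient of variation 0.
  Kurtosis is excess kurtosis; moments use the population (n) denominator;
  percentiles use R's default quantile type 7.
* **Wavelets**: one-level undecimated separable Haar, symmetric edge
  extension, subband labels with the first letter the x-axis filter.
  Feature extraction uses unit-gain low-pass normalization (LLL of a
  constant is that constant); the orthonormal option satisfies a Parseval
  identity with redundancy 8 (each axis doubles energy), which the tests
  verify.
* **Surface area**: no mesh library is part of the package's dependency
  set, and raw voxel-face counting overestimates smooth surfaces by a
  factor approaching 1.5. The estimator is the total variation of a
  Gaussian-mollified indicator (σ = 1 voxel, central differences on a
  padded grid), which converges to the true area for smooth bodies — the
  digital-ball sphericity check (radii 5 and 10 voxels, error shrinking and
  below 5%) pins the behaviour.

## 4. Robustness screening

ICC forms follow the Shrout–Fleiss ANOVA decomposition (see `?icc`). The
flattened study table leaves the study→form mapping ambiguous, so it is a
configurable argument with defaults matching column order: delineation →
ICC(1,1) (contouring methods as one-way random raters), attenuation →
ICC(3,1), motion → ICC(3,k) with k = 2 (average measures over the fixed
gated/ungated pair; whether "(3,2)" means average-measures over two
conditions or a third single-measures variant is not stated — the
average-measures reading is implemented). Stability is strict ICC > 0.9.
Negative ICCs are retained as computed; they simply fail the threshold. An
all-identical matrix (e.g., a constant feature under a mask-preserving
perturbation) is defined as ICC 1 with a warning — silenced in batch
screening, where such features count as stable. The robust set is the
intersection of the three stable sets; the Venn summary reports all seven
exclusive region counts overall and per family.

## 5. Modelling choices

* **Binarization**: event at or before the horizon vs. event-free follow-up
  reaching it; patients censored before the horizon are *excluded* from that
  endpoint (the `censored = "nonevent"` policy is available) — exclusion is
  the choice that biases neither class.
* **Horn's parallel analysis**: correlation eigenvalues vs. the 95th
  percentile of rank-matched eigenvalues from standard-normal data of the
  same shape, with the *sequential* rule (retain leading components while
  each exceeds its reference) — the counting rule admits isolated deep-rank
  exceedances and over-extracts on pure noise.
* **Grouping**: each standardized feature joins the retained component it
  correlates with most strongly in absolute value; zero-variance features go
  to a sentinel group excluded downstream.
* **Screening**: the group surrogate is the feature with the largest
  *oriented* Mann–Whitney AUC (ties break lexicographically); it survives
  only if its single-feature logistic Wald p < 0.05. The p-value source was
  an open choice; Wald is consistent with the downstream logistic framework.
* **Backward AIC**: drop the variable whose removal most decreases
  AIC = 2k − 2ℓ, stop when none does. Complete separation flags the model
  and re-estimates coefficients with a lightly ridge-penalized IRLS
  (λ = 0.01, intercept unpenalized) — a minimal fallback that keeps
  predictions finite without extra dependencies.
* **Cross-validation**: stratified five-fold, seeded; the *entire* selection
  pipeline (Horn → grouping → screening → AIC) re-runs inside every
  training fold, the stricter of the two readings and the one that avoids
  selection leakage. The reported model is refit on the full training
  cohort.
* **Model selection**: "best trade-off between largest mean AUC and smallest
  fold range" is made explicit as `mean − λ·range` with λ = 0.5,
  configurable; exact ties break by higher mean, then lexicographic
  endpoint id.
* **Validation**: the frozen model (training standardization and
  coefficients) is applied unchanged; the 95% CI uses DeLong's method.
* **Stratification**: the risk cutoff is the training-cohort median
  predicted probability, reused verbatim elsewhere; group medians are the
  first time the Kaplan–Meier estimate drops to ≤ 0.5; the split is tested
  with the Harrington–Fleming G-rho family (ρ = 0, i.e. log-rank, by
  default).
* **Seeds**: one master seed per run; stage seeds derive from it by a
  deterministic integer map (`derive_seed`), all below 2³¹.

## 6. Problem sizes used by the tests and the acceptance script

The suites run phantom extraction at grid 36³ (ROI ≈ 140 voxels on the
5.5 mm grid), image-based robustness studies at 8 phantoms per study,
oracle comparisons on ≤ 5³ toy grids and ≤ 30-patient AUC instances, and
modelling studies at n = 300 per cohort over 20 seeds — sizes chosen so the
whole battery stays interactive on a single core while every stage is
exercised end to end. The structural-headline scenario (all informative
features perturbation-sensitive → the robust-only pipeline finds no
significant candidates while the all-features pipeline recovers the designed
signal) runs at the same n = 300.

## 7. Known limitations

* Phantom CT is three-valued and co-registered by construction; no
  registration error, scatter, or reconstruction physics.
* The "manual" delineation variant is a stochastic boundary perturbation,
  not an observer model.
* Texture rosters are IBSI-aligned but not byte-identical to any specific
  software's roster; only the family counts (18/17/137/1232) are contracts.
* The ridge fallback under separation changes coefficient scale (not
  selection); models carrying the `separation` flag should be read with
  that in mind.
* Image-based cohorts are practical at tens of patients; the n = 300
  modelling studies use the feature-level generator, which shares the
  outcome model but bypasses image extraction.
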