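---
title: "Habitat clustering and intratumoral heterogeneity modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat clustering and intratumoral heterogeneity modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitomics)
```

## The problem and the model

Tumors are not homogeneous: high-grade lesions tend to contain spatially
distinct compartments ("habitats") — e.g. necrotic, high-water-content
regions visible on T2-weighted MRI and low-cellularity regions visible on
diffusion-weighted MRI. `habitomics` quantifies this intratumoral
heterogeneity (ITH) from paired T2WI/DWI tumor volumes and uses it for
binary grade prediction (low vs high, with intermediate grades merged into
high). The pipeline has five stages:

1. **Preprocessing.** Multiplicative bias-field correction, isotropic
   resampling, cohort histogram standardization, and DWI-to-T2WI
   registration by mutual information.
2. **Habitat clustering.** Per sequence, the within-VOI voxel intensities
   are z-scored and partitioned by K-means; K is chosen once for the whole
   cohort by the elbow of the pooled SSE curve. Habitats are ordered by
   descending cluster mean, so habitat 1 is always the high-signal
   subregion.
3. **Subregion radiomics.** An IBSI-style feature engine computes
   first-order, shape and five texture-matrix families (GLCM, GLRLM, GLSZM,
   GLDM, NGTDM) over a 21-image-type filter bank, for the whole tumor on
   each sequence and for each habitat. With the full bank each region
   yields 14 shape + 90 × 21 = 1904 features (378/14/441/336/336/294/105
   per class).
4. **Selection and subregion models.** Per subregion: a chi-square filter
   on median-dichotomized features (p < 0.05), LASSO-penalized logistic
   regression with the penalty chosen by 10-fold cross-validated deviance
   (minimum rule), then a maximum-likelihood logistic model. The four
   subregion probabilities are aggregated into a patient-level **ITH
   index** — the unweighted mean over a chosen subregion subset — and the
   subset is selected among 13 admissible candidates (4 singletons plus the
   9 subsets containing at least one subregion from each sequence) by
   internal-validation AUC, then wrapped in a training-fitted logistic
   recalibration.
5. **Final models and evaluation.** Seven logistic models on the block
   unions of clinical/laboratory/imaging covariates, whole-tumor radiomics,
   and the ITH index; evaluated by DeLong AUC with 95% CI, threshold
   metrics at the training Youden cut, DeLong paired tests, calibration and
   decision curves, and exact linear Shapley attributions.

## What the synthetic cohort emulates

No patient data ship with the package; `generate_cohort()` builds a
phantom cohort that reproduces the *structure* the method relies on, with
ground truth stored for every planted quantity:

- **Geometry.** Each tumor is a sphere deformed by a smooth random radial
  perturbation (±12%), placed centrally in a 30 × 30 × 22 voxel patch at
  1.2 × 1.2 × 1.6 mm spacing — the cropped peri-tumoral field of view used
  in radiomics practice. Radii are drawn from 7–11 mm.
- **Habitats.** Habitat 2 is planted as one or more coherent blobs
  (a thresholded smooth Gaussian random field), not salt-and-pepper noise,
  so clustering recovers spatially coherent subregions. The habitat-2
  volume fraction is grade-dependent: Beta-distributed around 0.25
  (low grade) or 0.40 (high grade) with concentration 25. These effect
  sizes are free parameters of the phantom — chosen once as plausible — not
  estimates of any real cohort.
- **Intensities.** Within-habitat voxel values are habitat mean + correlated
  noise; means are ordered so habitat 1 is bright on both sequences
  (T2WI 300/180, DWI 250/140, SD 25, background 80, arbitrary units). The
  ≥ 3-SD separation makes the within-VOI histogram bimodal, which the
  clustering stage depends on.
- **Texture.** Gaussian-smoothed white noise whose smoothing length is set
  from a target lag-1 autocorrelation (corr(d) = exp(−d²/4σ²)); the target
  is grade-dependent (0.30 low vs 0.55 high) and jittered per patient on
  the logit scale (SD 0.5), so grades overlap rather than separate
  trivially. This measurably shifts GLCM/NGTDM features without modelling
  any pulse-sequence physics.
- **Artifacts.** `apply_artifacts()` multiplies each sequence by a random
  quadratic bias field (relative amplitude 0.2 by default) and displaces
  DWI by a 3 mm rigid shift plus a 1 mm smooth warp, storing both as ground
  truth for the preprocessing contracts.
- **Covariates.** Table-style binary covariates are Bernoulli draws with
  grade-conditional prevalence. Two variables carry real effects —
  an infiltrative tumor margin depleted in high grade (0.55 vs 0.25) and a
  targetoid T2WI signal pattern enriched in high grade (0.45 vs 0.75) —
  because only margin- and T2-pattern-type variables are meant to survive
  multivariable screening; all other covariates have equal prevalence in
  both grades and act as nulls. Laboratory markers are drawn directly as
  dichotomized calls at their conventional positivity thresholds
  (CA19-9 > 39 U/mL, CEA > 4.7 ng/mL, AFP > 7 ng/mL, CA12-5 > 35 U/mL).
- **Reader tables.** `generate_reader_tables()` emits paired continuous
  measurements (truth + reader noise) and categorical calls (truth flipped
  with a set probability), giving closed-form expected ICC and kappa.

All randomness flows from one root seed through named per-patient
substreams, so regeneration is exact and order-independent.

**What the phantom does not capture:** real liver anatomy, scanner- and
site-specific intensity distributions, partial-volume effects at real
resolutions, segmentation variability, and correlated covariate structure.
Passing tests on this cohort demonstrate that the pipeline's machinery is
correct and that planted effects of realistic magnitude are recoverable;
they say nothing about clinical performance on real patients.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tumor_radius_range` | 7–11 | mm | desk-scale lesions that still contain hundreds of voxels per habitat |
| `habitat_fraction_low/high` | (0.75, 0.25) / (0.60, 0.40) | fraction | grade effect on habitat composition |
| `intensity_sd` | 25 | a.u. | ~4.8 SD habitat separation, comfortably bimodal |
| `texture_correlation_low/high` | 0.30 / 0.55 | lag-1 correlation | grade effect on texture, overlapping across patients |
| `bias_amplitude` | 0.2 | fraction | typical visible shading |
| `misalignment` | 3 mm shift + 1 mm warp | mm | inter-sequence misregistration scale |
| K-means | k-means++, 25 restarts, 300 iterations | — | reproducible best-of-restarts SSE |
| elbow scan | K = 1..8 | clusters | covers all plausible habitat counts |
| `bin_width` | 25 | intensity units | ~10 levels on the phantom's intensity scale |
| LASSO penalty | minimum CV deviance, 10 folds | — | selects aggressively; the one-SE rule would underfit the small blocks |
| split | 8:2 stratified | — | training/internal-validation convention |

## Numerical and design choices

- **Bias correction** estimates a cubic log-domain polynomial field by
  robust (bisquare) regression, so anatomy acts as outliers to the smooth
  field, and rescales it to unit geometric mean inside the mask. This is a
  deliberately simple stand-in honouring the same contract as dedicated
  bias-correction algorithms (coefficient-of-variation reduction on
  known-bias phantoms); any such implementation can be swapped in behind
  `correct_bias()`.
- **Histogram standardization** uses the classic two-stage decile-landmark
  method with percentiles 1, 10, ..., 90, 99 estimated by the inverse-ECDF
  (type-1) quantile. Type-1 quantiles commute with monotone maps, which
  makes the transform exactly idempotent rather than idempotent only up to
  interpolation error. Landmarks are learned on training volumes only and
  frozen.
- **Resampling** interpolates intensities trilinearly and masks by nearest
  neighbor. The contracts (preserved extent, integer labels) do not depend
  on the interpolant order, and keeping interpolation first-order avoids
  ringing on the small phantom patches.
- **Registration** is DWI (moving) onto T2WI (fixed): center-of-mass
  initialization, a coarse-to-fine translation grid, Nelder-Mead refinement
  of the mutual-information metric (32-bin joint histogram), and an
  optional demons-style deformable stage with Gaussian regularization. The
  deformable update runs on rank-equalized intensities so it matches
  geometry rather than the sequences' different contrast scales. An
  optimizer failure returns the identity transform with a warning rather
  than aborting.
- **Elbow rule.** The selected K maximizes the perpendicular distance from
  the (K, SSE) point to the chord joining the curve's endpoints after
  min-max normalizing both axes; ties break toward smaller K, and
  non-monotone curves (possible across independent restarts) are
  isotonically regressed first with a warning. K is chosen once on the
  cohort-averaged normalized curve, because the four named subregion models
  require a common K.
- **Discretization.** Fixed bin width anchored at the within-region
  minimum. Derived image types reuse the configured width rescaled by the
  ratio of their robust (1st–99th percentile) range to the original's, so
  wavelet or LoG outputs on much smaller numeric scales still quantize into
  a comparable number of levels instead of collapsing to one bin.
- **Filter bank.** The 21 image types (original, 8 undecimated Haar
  sub-bands, LoG at 1–4 mm, four monotone intensity transforms, gradient
  magnitude, three LBP-3D-style maps) are fixed so the per-class feature
  counts come out exactly at the printed budget; the texture families are
  computed with distance-1 symmetric GLCM averaged over the 13 unique 3D
  directions, 26-connectivity zones/dependence, and 0·log 0 = 0
  conventions. Degenerate regions (single gray level) yield defined
  entropy-type features and flagged-undefined correlation.
- **Shape features** use the face-count surface area (exact for
  axis-aligned boxes, an over-estimate for curved surfaces) and
  eigenvalue-based axis lengths; a single-voxel region returns all-NA with
  a warning.
- **Candidate enumeration.** "Combinations of the four subregion scores"
  is operationalized as all singletons plus every subset containing at
  least one subregion from each sequence: 4 + 4 + 4 + 1 = 13 candidates;
  the two within-sequence pairs are excluded. The ITH combiner is the
  unweighted probability mean with a training-fitted logistic
  recalibration; singleton subsets reduce to the subregion probability.
- **Final models** are fitted with a weak L2 penalty (λ = 1/n on
  standardized inputs), the default behaviour of the logistic-regression
  toolkits these fused clinical-radiomic models are conventionally built
  with; it keeps the high-dimensional fused blocks stable without
  materially shrinking the single-block models. Decision thresholds are
  training-set Youden cuts only.
- **Leakage guards.** Chi-square medians, LASSO folds and scaling,
  standardization constants, habitat-model calibration and thresholds are
  all computed on training rows; the internal-validation cohort only ever
  scores candidates.
- **SHAP** uses the exact closed form for linear models with an
  independent-feature background (coefficient × deviation from training
  mean, on the log-odds scale), so attributions are deterministic and sum
  exactly to the patient's log-odds minus the background log-odds.
- **Agreement statistics.** ICC is the two-way random-effects,
  absolute-agreement, single-measurement form; kappa is unweighted. Both
  conventions are stated because several variants exist.

## Problem sizes

The package is exercised at desk scale: the default demo cohort has 60
patients; structural contracts run on single patients; the
parameter-recovery study uses 5 replicate cohorts of 300 patients with the
original-image feature set (the full 21-type bank is exercised separately on
one region, where it reproduces the 1904-feature budget). These sizes give
stable Monte-Carlo estimates for every asserted quantity while keeping a
full test run in the minutes range.

## Known limitations

- The bias model is polynomial; pathologically high-frequency shading would
  not be removed.
- The affine registration stage defaults to translation-only refinement;
  rotations/scalings are supported via `type = "affine"` but the synthetic
  misalignment model does not generate them.
- The face-based surface area biases sphericity downward for smooth shapes;
  comparisons are therefore only meaningful within this engine, which is
  the usual caveat between radiomics implementations.
- Feature values are not harmonized across "scanners"; the phantom has no
  site effects to correct.
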