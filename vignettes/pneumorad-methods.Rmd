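---
title: "Methods: radiomics and blood-biomarker modeling of ICI-associated lung inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics and blood-biomarker modeling of ICI-associated lung inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumorad)
```

# The analysis in one paragraph

A treated cohort of mice carries a continuous lung-inflammation score
(CD45+ cell infiltration measured by immunohistochemistry after therapy).
The score is dichotomized at its median into low/high groups; pretreatment
measurements — CT and MRI lung radiomics, complete blood counts and serum
cytokines — are screened one at a time by two-group ANOVA, pruned for
mutual Pearson correlation, and the survivors enter a binary logistic
model of the high-inflammation state that is evaluated by stratified
two-fold cross-validation with ROC averaging. `pneumorad` implements each
of these stages as a separately testable function and adds a synthetic
cohort/phantom generator so the whole chain runs without animal data.

# The model

With predictors $x$ (standardized internally on training statistics) and
label $y \in \{0,1\}$ for low/high inflammation, the model is ordinary
binomial logistic regression with an intercept ("model constant"):

$$\operatorname{logit} P(y = 1 \mid x) = \beta_0 + \beta^\top x .$$

`fit_logistic()` maximizes the Bernoulli log-likelihood by iteratively
reweighted least squares (IRLS, convergence tolerance $10^{-10}$ on the
coefficient step, at most 100 iterations). Two numerical realities of a
15-subject cohort shape the implementation:

* **Separation.** With 3–5 predictors and 7-subject training folds the
  classes are frequently linearly separable and the MLE diverges. When a
  $\lambda = 0$ fit fails to converge or drives a standardized slope past
  20, the fit is repeated with a small ridge penalty
  ($\lambda = 10^{-3}$ on standardized slopes, never on the intercept)
  and flagged (`separation = TRUE`). This is a documented, reproducible
  stabilizer: unpenalized software would instead report arbitrarily large
  coefficients at an interior iteration. Cross-validation uses
  $\lambda = 10^{-3}$ throughout for the same reason.
* **Standardization.** Features are z-scored with training-fold statistics
  only (no leakage into validation folds); coefficients are mapped back to
  the input scale for reporting.

The fitted object is a classic S3 model with `print`, `summary` (Wald
table from the penalized Fisher information), `coef`, `predict`
(`link`/`response`), `residuals` (deviance, Pearson, response),
`simulate` and `plot` (in-sample ROC) methods.

## Evaluation

`two_fold_cv()` draws a *stratified* random split — for 7 low / 8 high
that yields folds of 7 and 8 with both classes in each fold by
construction, which an unstratified split cannot guarantee at this size.
Each fold is used once for fitting and once for validation. Per-fold ROC
curves come from a threshold sweep with ties grouped; the trapezoidal AUC
then equals the rank-based (Mann–Whitney, ties = 1/2) AUC exactly, which
the tests verify on 500 random instances. Two summaries are reported,
because "the average of the two ROC curves" is ambiguous: the arithmetic
mean of the two fold AUCs (`mean_auc`) and the AUC of the vertically
averaged curve on an FPR grid of 0 to 1 in steps of 0.01
(`average_curve_auc`). Vertical averaging interpolates each polyline
linearly and takes the upper envelope of vertical segments only at exact
grid hits; interpolating *across* a vertical segment would bias degenerate
curves (a perfect and a null curve must average to 0.5, which is a test).

# Feature selection

* `dichotomize_by_median()` labels a subject high when its value is
  $\ge$ the median, so 15 distinct values give 7 low / 8 high with the
  median subject in the high group. (The printed cohort descriptives this
  emulates contain an impossible combination — a treated-cohort median
  lying strictly between the low group's maximum and the high group's
  minimum — so the package implements the standard median and documents
  the discrepancy here rather than reproducing it.)
* `anova_p()` is the two-group one-way ANOVA F test with 1 and $n-2$
  degrees of freedom, algebraically identical to the pooled two-sided
  t-test ($F = t^2$, verified to $10^{-10}$).
* `select_features()` drops features with $p >$ `p_threshold` (default
  0.1, as in the source design), orders survivors by ascending $p$ with
  lexicographic tie-break (the original procedure is silent on ties; a
  name-based tie-break makes the kept set invariant to input column
  order, which is tested), and keeps each greedily unless
  $|r| >$ `r_cutoff` (default 0.5) with an already-kept feature — i.e.
  of a correlated pair the larger-$p$ member is dropped. Constant
  features (e.g. a detection-limited cytokine) are dropped as degenerate
  with a recorded reason. No multiple-testing correction is applied by
  default, matching the emulated design; `adjust = "BH"` is available.
  One caution: the intuition "raising `r_cutoff` can only enlarge the
  kept set" is *not* a theorem for greedy pruning (a looser cutoff can
  keep a hub feature that then blocks several later ones), so only the
  provable monotonicity — tight-screen survivors are a prefix of the
  loose-screen greedy order — is asserted as a property.

# Radiomics

## Catalogue

The feature vector is frozen at exactly 92 names per modality
(`feature_catalogue()`, mirrored in
`inst/extdata/feature_manifest.json`): 8 geometric + 20 first-order +
14 GLCM × 4 distances + 6 triplet + 2 histogram-shape extras. The
catalogue honors the four stated feature families and the stated total;
the identity of every member is this package's own documented
reconstruction, since no public list exists. Specific conventions:

* **Ng = 64 equal-width gray levels.** The emulated study's co-occurrence
  entropies sit at 12.1–12.3 bits, just under the $2\log_2 64 = 12$-bit
  ceiling of a 64-level *joint* distribution only if entropy is read in
  bits on a 64-level quantization — hence $\log_2$ and Ng = 64.
* **Kurtosis is Pearson (non-excess).** A normal sample gives 3; the
  emulated CT kurtosis range (1.9–6.6) brackets 3, consistent with this
  convention. The mathematical floor is 1 (two-point distributions).
* **GLCM.** Pairs at lattice distance $d \in \{1,2,3,4\}$ along the 13
  unique 3D directions, counted in both senses (symmetrization), pooled
  into a single matrix per distance, normalized to sum 1. Pooling before
  feature computation (rather than averaging 13 per-direction feature
  values) is the common convention and makes the features invariant under
  90° axis-aligned rotations for isotropic spacing (tested). Offsets are
  voxel-lattice steps: anisotropic CT spacing (0.4 × 0.4 × 0.6 mm) is
  used as-is rather than resampled, the simplest deterministic choice.
* **Third-order features.** Collinear triplets $(v, v+du, v+2du)$ fully
  inside the mask, symmetrized under reversal
  ($T_{ijk} = T_{kji}$), normalized; entropy, energy, contrast
  $\sum T \,(|i-j|+|j-k|)^2/4$, homogeneity, maximum probability and
  cluster tendency. Both builders are verified against exhaustive
  brute-force enumeration on 200 random small volumes.
* **Geometric features.** Surface area is face-counting over boundary
  voxels. That estimator inflates smooth surfaces by the Manhattan
  staircase factor (a digitized ball's face-counted area tends to
  $6\pi r^2$, 3/2 of the true $4\pi r^2$), so face-counted sphericity of
  a ball tends to 2/3 — *below* a cube's $(36\pi)^{1/3}/6 \approx 0.806$.
  The tests pin these closed forms rather than the naive "ball is
  rounder" ranking, which face counting inverts. The stated 8-member
  geometric list did not fit in 8 slots (volume, surface, S/V,
  sphericity, max diameter, per-axis extents, elongation, flatness count
  10), so per-axis extents were folded into a PCA major-axis length.
* **MRI normalization.** Z-score within the mask, then a linear map of
  the masked range onto [0, 255]; idempotent and invariant to global
  affine intensity changes. Histogram-landmark alternatives exist but are
  not reconstructible here; the hook is `config$normalize`.

## CT segmentation

`segment_lungs_ct()` keeps voxels inside the `low`–`high` window (default
800–1200), restricted to the bounding box of the largest bright
(`> high`) component as a body-interior proxy, removes 26-connected
components below `min_component_voxels` (default 50), and applies a
deterministic trachea proxy: drop any component whose principal-axis
elongation exceeds 4 while its centroid lies within the central 20% of
the left–right axis (the emulated procedure removed the trachea
manually; a rule is testable). `keep_all_components = TRUE` disables the
proxy. The 800–1200 window cannot be standard Hounsfield units (lung
parenchyma is near −800 HU); the package therefore treats CT intensities
as raw scanner units on an air-near-zero offset scale, records the
convention in the volume metadata, and leaves both thresholds
configurable for true-HU data. Segmentation is idempotent on its own
masked output (tested), and empty results raise rather than returning an
empty mask.

# The synthetic-data module

The generator defines the study conditions under which all statistical
claims are tested; it is first-class, tested code.

**Tabular cohorts** (`generate_tabular_cohort()`): 7 low / 8 high
subjects by default. CD45 is drawn per group from normal distributions
with means/SDs 0.176/0.041 (low) and 0.324/0.055 (high); six informative
biomarkers (NLR 0.7±0.1 vs 0.6±0.1, GM-CSF 8.8±0.6 vs 11.7±2.2, CT
average gray 278.4±9.0 vs 289.9±15.3, CT histogram kurtosis 2.6±0.4 vs
3.8±1.7, CT co-occurrence entropy 12.1±0.1 vs 12.3±0.1, MR histogram
kurtosis 6.1±3.3 vs 3.7±1.6) are drawn from group normals. All group
distributions are normal because only moments are published. Physical
floors (CD45 ≥ 0, counts ≥ 0, NLR > 0) are enforced by resampling, but
only where the floor is far out in the tail; the histogram-kurtosis
columns are drawn untruncated because flooring at the mathematical
minimum would visibly shift the printed moments, and moment fidelity is
the generator's contract (sample moments recover their parameters within
3 SE at n = 10,000 per group, tested). The remaining CBC/cytokine panel
columns are drawn uniformly within their published cohort min–max,
identically in both groups, since they were found non-significant;
RANTES is constant at its detection-limit value and is deliberately left
for the screen to discard. Neutrophils are set to $NLR \times Lym$ so the
*derived* ratio carries the planted effect. Nuisance radiomics columns
(N(0,1), identical across groups) fill each modality to 92 features —
89 for CT (3 informative) and 91 for MRI (1 informative).

**Imaging phantoms** (`generate_phantom()`): two ellipsoidal lungs
(semi-axes 3.5 × 4 × 7 mm each, combined ≈ 821 mm³, matching the
emulated mean bilateral lung volume of 823.5 mm³ to within
discretization) inside a bright body ellipsoid on an air background, at
CT spacing 0.4 × 0.4 × 0.6 mm (64 × 64 × 40 grid) and MRI 0.5 mm
isotropic (52 × 52 × 48). Lung texture is a smoothed Gaussian field
(FFT-based blur, correlation length `smooth_mm`) plus an independent
two-component scale-mixture noise. The kurtosis handle is the mixture's
wide/narrow *sd ratio* at fixed tail weight 0.05 — not the mixing weight,
because the kurtosis of a two-normal scale mixture is non-monotone in
the weight over its useful range, whereas it is strictly increasing in
the sd ratio (ratio 1 recovers a normal, kurtosis 3); the monotone sweep
is a tested property. Group-dependent texture parameters give the two
groups different smoothing, kurtosis shape, and (CT) a small level
shift, and the ground-truth mask is exactly the voxelized ellipsoid
predicate. With a shared seed the two groups share the underlying random
fields, so masks are identical and only the texture transform differs.

**What the phantoms do not emulate:** anatomy (no airways, vasculature,
lobes or atlas geometry), scanner physics (no beam hardening, partial
volume, bias fields or acquisition noise spectra), registration error,
or any dependence of image texture on actual tissue inflammation. A
passing pipeline on phantoms demonstrates correctness of the
computational chain under known ground truth, not biological validity on
real scans.

# Problem sizes and numerical tolerances

Co-occurrence structures are validated to sum to 1 within $10^{-9}$;
oracle equivalences (brute-force enumeration, rank-AUC, $F = t^2$) are
asserted at $10^{-10}$–$10^{-12}$. The statistical suites use: 200
random small volumes for the texture oracles, 500 random instances for
the AUC equivalence, 500 seeded 15-subject cohorts for screen-recovery
rates, 200 cohort seeds for the cross-validated AUC distribution (real
and label-permuted), and n = 2000 with 11 replicate draws (median
readout) for logistic parameter recovery — sizes chosen so the whole
suite and the acceptance script each run in minutes on one CPU while
keeping Monte-Carlo error well inside the asserted margins.

A note on the screen-recovery conditions: recovery is measured under the
*faithful* pipeline — labels re-derived by median dichotomization of the
generated CD45 (which relabels a few subjects relative to their
generating group and attenuates effects), and all numeric columns
including the 180 nuisance radiomics as screen candidates (which exposes
the informative features to chance $|r| > 0.5$ collisions at n = 15).
Both mechanisms substantially reduce how often NLR and GM-CSF survive
into the kept set compared to a naive power calculation at the planted
moments; the acceptance suite reports the measured rates as-is.

# Known limitations

* The 92-feature catalogue is a reconstruction honoring the stated
  families and count; member-level comparability with the original
  in-house extractor is not claimed, and no IBSI certification is
  implied.
* Logistic coefficients from 15 subjects with a ridge stabilizer are not
  comparable coefficient-by-coefficient to an unpenalized SPSS fit, and
  the original per-animal data are not available, so published AUCs are
  echoed only qualitatively (distributionally, over synthetic cohorts).
* MRI segmentation is not automated; MRI masks are required inputs, as
  in the emulated workflow (manual contours supported by CT
  co-registration).
* The CT intensity convention is an explicit assumption (offset scale,
  air ≈ 0); on calibrated HU data the default window must be changed.
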