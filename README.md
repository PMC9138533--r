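# pneumorad

Radiomics and blood-biomarker modeling of immune-checkpoint-inhibitor (ICI)
associated lung inflammation in small-animal cohorts.

Checkpoint-inhibitor-induced pneumonitis is a rare but potentially
life-threatening immune-related adverse event, and there is no accepted way
to identify at-risk subjects before therapy begins. In the preclinical
setting the question becomes: can *pretreatment* data — CT/MRI lung
radiomics, complete blood counts (CBC) and serum cytokines — predict which
animals will develop high lung inflammation (measured post-mortem as CD45+
cell infiltration) after combined radiotherapy + anti-PD-1 treatment?
`pneumorad` implements that analysis end to end as a tested, reusable R
pipeline, together with a synthetic-data module (tabular cohorts and
textured two-lung imaging phantoms) so that every stage can be exercised,
tested and benchmarked without any animal data.

It is aimed at quantitative-imaging and immunotherapy-toxicity researchers
who want a small, fully reproducible reference implementation of this class
of radiomics study design.

## What it computes

**Radiomics.** For a masked volume the package extracts a frozen catalogue
of exactly 92 features per modality: 8 geometric (volume, face-counted
surface area, sphericity, maximum 3D diameter, principal-axis shape), 20
first-order histogram features (mean "average gray", Pearson kurtosis with
normal → 3, log2 entropy, percentiles, ...), 14 gray-level co-occurrence
(GLCM) features at each lattice distance d ∈ {1,2,3,4} over the 13 unique
3D directions pooled and symmetrized (P = Pᵀ, ΣP = 1, Ng = 64), 6
third-order features over collinear voxel triplets (T[i,j,k] = T[k,j,i]),
and 2 histogram-shape extras. MRI intensities are z-scored and mapped onto
[0, 255] inside the mask first, making MRI features invariant to global
affine intensity changes. CT lungs can be segmented automatically by the
800–1200 intensity window (air-near-zero offset scale) with
connected-component cleanup and a deterministic trachea-proxy filter.

**Statistics.** The cohort is dichotomized at the median CD45 value
(15 subjects → 7 low / 8 high). Candidate features are screened by
two-group one-way ANOVA (F = t², kept at p ≤ 0.1) and pruned greedily in
ascending-p order at Pearson |r| ≤ 0.5. The inflammation model is binary
logistic regression with a model constant,

  logit P(high) = β₀ + βᵀx,

fitted by IRLS with a small ridge (λ = 1e-3) fallback when the tiny
training folds are linearly separable. Evaluation is stratified two-fold
cross-validation (train on 7, validate on 8, then reverse), with per-fold
ROC curves, their vertical average on an FPR grid, and the mean AUC.
The canonical CT model uses {average gray, histogram kurtosis,
co-occurrence entropy, NLR, GM-CSF}; the MRI model uses {histogram
kurtosis, NLR, GM-CSF}, where NLR is the neutrophil-to-lymphocyte ratio
derived from the CBC.

## Worked example

```r
library(pneumorad)

## synthetic 15-subject cohort at the published group moments
cohort <- generate_tabular_cohort(cohort_spec(seed = 11))
cohort$NLR <- derive_ratios(cohort)$NLR
labels <- dichotomize_by_median(cohort$cd45)
table(labels)
#> labels
#>  low high
#>    7    8

## ANOVA screen + correlation pruning on a candidate panel
select_features(cohort,
  c("NLR", "GM_CSF", "ct_average_gray", "ct_hist_kurtosis",
    "ct_cooc_entropy", "mr_hist_kurtosis", "WBC", "PLT", "KC", "TNF_a"),
  labels)
#> Feature selection: 10 candidates, 4 kept (p <= 0.1, |r| <= 0.5)
#>   NLR                      p = 0.0009952
#>   ct_cooc_entropy          p = 0.005394
#>   ct_average_gray          p = 0.008388
#>   ct_hist_kurtosis         p = 0.05463

## cross-validated CT model
two_fold_cv(cohort,
  c("ct_average_gray", "ct_hist_kurtosis", "ct_cooc_entropy", "NLR", "GM_CSF"),
  labels, seed = 2)
#> Two-fold cross-validation (n = 15; folds 7/8)
#>   features: ct_average_gray, ct_hist_kurtosis, ct_cooc_entropy, NLR, GM_CSF
#>   fold AUCs: 1.000, 1.000; mean AUC = 1.000; averaged-curve AUC = 1.000
```

The screen keeps NLR and three CT radiomics here; GM-CSF happens to fall to
the correlation pruning for this seed, and this particular split scores
perfectly — single 15-subject cohorts are noisy in both directions.
Averaged over 200 cohort seeds the CT model's mean cross-validated AUC is
about 0.87 and the MRI model's about 0.82, collapsing to ≈ 0.50 when the
labels are permuted (see below).

The imaging arm works the same way from phantoms:

```r
ph  <- generate_phantom(phantom_spec("CT", seed = 3), "high")
seg <- segment_lungs_ct(ph$volume, 800, 1200)
seg
#> <roi_mask> 64x64x40, 8481 foreground voxels (814.2 mm^3)
round(extract_features(ph$volume, ph$mask)[
  c("geom_volume_mm3", "fo_mean", "fo_kurtosis", "glcm_d1_entropy")], 3)
#> geom_volume_mm3         fo_mean     fo_kurtosis glcm_d1_entropy
#>         819.456        1011.849           3.184          10.097
```

A whole run — synthesize, segment, extract, merge blood work, select,
model — is one call: `run_pipeline(run_config(cohort_seed = 1), "runs/demo")`,
or from a shell via the thin wrapper `inst/cli/pneumorad.R`.

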