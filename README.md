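# habitatMSI

Habitat analysis of lung nodules at non-contrast CT: density-based
intratumoral subregion discovery and **Multi-regional Spatial Interaction
(MSI)** feature extraction, wired into a complete grade-prediction harness.
The package targets researchers in quantitative imaging who want to quantify
*how* the tissue compartments of an invasive pulmonary adenocarcinoma (IPA)
are arranged — not just how much of each exists — and relate that spatial
architecture to histological grade (IASLC low grade I/II vs high grade III).

## The method

1. **Subregion discovery.** Each lesion volume-of-interest is normalized to
   the lung window (width 1500 HU, level −600 HU, so HU in \[−1350, 150\] map
   to \[0, 1\]) and oversegmented into ≤ 100 SLIC supervoxels. Supervoxel
   phenotypes (mean normalized intensity) from the *training* cohort are
   pooled and clustered by a 1-D Gaussian mixture; the subregion count k is
   chosen by the elbow of the within-cluster SSE curve. With three
   components the canonical labels are: subregion 1 = highest attenuation
   (dense, "sub-solid" tissue, ≈ −73 HU), subregion 2 = lowest (air-like,
   lepidic/alveolar, ≈ −827 HU), subregion 3 = intermediate (≈ −424 HU).

2. **MSI matrix.** For a label map with k subregions plus background 0, the
   (k+1)×(k+1) matrix N counts unordered face-adjacent voxel pairs by their
   label pair, excluding pairs wholly in background:

   N(i, j) = #{ neighboring voxel pairs with labels {i, j}, at least one in-mask }

   Diagonal entries reflect subregion volume; off-diagonal entries quantify
   inter-subregion adjacency. From N the package derives 33 named
   first-order features (volume proportions, border proportions
   `MSI_border_proportion_i_j = N(i,j)/B` with B the total inter-region
   border count, conditional border proportions, boundary shares, interior
   ratios, pair entropy, …) and 5 second-order co-occurrence statistics
   (contrast, correlation, energy, homogeneity, entropy) on P = N/ΣN.

3. **Modeling harness.** SMOTE rebalancing (perc.over = 200,
   perc.under = 155, training cohort only), Z-score standardization fitted
   on training data, RFE + LASSO feature selection (10-fold CV), a 4
   preprocessor × 5 classifier grid selected on validation AUC, and
   evaluation by ROC/AUC with DeLong confidence intervals and tests,
   calibration + Brier score, decision-curve analysis, exact Shapley
   attributions, and tumor-size subgroups (≤20, >20–30, >30 mm).

No public imaging accession exists for the source cohort, so the package
ships a seeded synthetic nodule generator (`generate_nodule()`,
`generate_cohort()`) that reproduces the study's structure: three density
components at the published mean attenuations, grade-dependent composition
(high grade: more dense, less air-like tissue, peripherally displaced
air-like regions), Table-1-style covariates, and a 161/66/128 cohort split
with 18.6% high-grade prevalence.

## Worked example

```r
library(habitatMSI)

cfg <- pipeline_config(seed = 2024,
                       cohort = cohort_recipe(n_train = 60, n_val = 25, n_test = 25),
                       out_dir = tempfile())
res <- run_pipeline(cfg)

res$results$subregions$model
#> <subregion_model> k = 3 subregions (candidates 1..6)
#>   canonical label: mean intensity (weight)
#>     1: 0.8473 (0.269)
#>     2: 0.3533 (0.151)
#>     3: 0.6172 (0.580)

res$results$model$model
#> <grade_model> box_cox + random_forest (validation AUC 1.000, threshold 0.529)
#>   4 features: volume_proportion_1, MSI_border_proportion_1_3, interior_ratio_1, pair_entropy

res$results$evaluation$test$report
#> <eval_report> cohort test (n = 25), threshold 0.529
#>   AUC 1.000 (1.000-1.000)  Brier 0.023
#>   accuracy     0.960 (0.805-0.993)
#>   sensitivity  0.800 (0.376-0.964)
#>   ...
```

The mixture recovers three subregions whose mean normalized intensities map
back to ≈ −79 / −820 / −424 HU — the dense, air-like and intermediate
habitats — and the grade model separates the synthetic grades from MSI
features alone. (On the deliberately well-separated synthetic cohort the
AUC is near 1; the generator's class separation is configurable through
`cohort_recipe()`.)

Single operations are equally accessible:

```r
nod <- generate_nodule(nodule_recipe("high", diameter_mm = 20, seed = 7))
voi <- crop_voi(nod$volume, nod$mask)
sv  <- compute_supervoxels(window_normalize(voi$volume), voi$mask)
required_sample_size(c(sensitivity = 0.80, specificity = 0.70))$total
#> [1] 224
```

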