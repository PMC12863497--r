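---
title: "Habitat clustering and MSI features: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat clustering and MSI features: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind habitatMSI, the
parameters that matter, the numerical choices, and what the synthetic
cohort can and cannot tell you about real data.

## The problem

Invasive pulmonary adenocarcinoma is graded histologically (IASLC grade 3 =
at least 20% solid, micropapillary or complex glandular patterns). On
non-contrast CT, such tumors are mixtures of tissue compartments with very
different attenuation: dense cellular regions, air-containing lepidic
regions, and mixed intermediate tissue. Whole-lesion radiomics averages
over this structure. The habitat/MSI approach instead labels every voxel
with its density compartment and summarizes how the compartments touch one
another — the premise being that aggressive growth remodels the internal
architecture (consolidated dense cores displacing air-rich tissue) in ways
that adjacency statistics capture and volume fractions alone do not.

## Subregion discovery

**Windowing.** Voxels are clipped to the lung window (width 1500 HU, level
−600 HU → \[−1350, 150\] HU) and scaled affinely to \[0, 1\]. Saturation is
deliberate: "min–max" normalization after windowing is only well defined if
out-of-window values pin to 0/1. The transform is monotone and idempotent
on re-expressed values (tested).

**Resampling.** `resample_isotropic()` provides trilinear (intensities) and
nearest-neighbor (masks, label maps) resampling with the output-dimension
convention `round(dim * spacing / target)`. The subregion pipeline runs on
the native grid when it is already isotropic — the synthetic generator
emits 1 mm³ voxels, so resampling is an identity there. Trilinear
interpolation is the package's interpolation choice for intensity volumes;
label safety (a binary mask stays binary) is tested.

**Supervoxels.** 3-D SLIC restricted to the mask (compiled in C++):
distance D² = ΔI² + m²·(Δs/S)² with intensity in \[0, 1\], spatial distance
in mm, S the expected supervoxel pitch, and compactness m = 0.1 on the unit
intensity scale. Defaults: `n_segments = 100` per lesion, 10 iterations.
After convergence every connected fragment becomes its own supervoxel and
fragments are merged smallest-first into their most-contacted neighbor
until at most `n_segments` remain — this guarantees the two properties the
rest of the pipeline relies on: supervoxels exactly partition the mask, and
each one is 6-connected. The supervoxel phenotype is the mean normalized
intensity: the minimal choice consistent with a density-based habitat
definition; the phenotype table is a data frame and can be extended.

**Cohort-level mixture.** Training-cohort phenotypes are pooled and fitted
with 1-D unequal-variance Gaussian mixtures for each candidate k (default
1–6). Each fit is an EM run (tolerance 1e-6, max 500 iterations) restarted
from 10 k-means initializations, keeping the best log-likelihood; the
restarts matter, because a single deterministic initialization occasionally
lands in a poor local optimum at exactly the k under comparison and
corrupts the model-selection curve. For the elbow we record the
within-cluster SSE of phenotypes under hard maximum-posterior assignment
(the mixture log-likelihood itself is monotone in k with no natural elbow
scale). The recorded curve is monotonized with a running minimum, since
with finitely many restarts EM can in principle return a slightly worse
optimum at larger k.

**Elbow criterion.** `select_k_elbow()` maximizes the curvature (second
difference) of the SSE profile *on the log scale*, ties toward smaller k.
The log scale is a deliberate design decision: raw second differences are
dominated by the first drop of the curve and systematically return k = 2
for any three roughly equidistant well-separated clusters (for clusters at
0.1/0.5/0.9 with sd 0.02 the raw-SSE curve is ≈ \[64, 16, 0.2, 0.2\]n/600,
whose raw curvature peaks at k = 2 even though k = 3 is unambiguous).
Relative drops locate where adding a cluster stops paying off; on the log
scale the same rule reproduces both the textbook worked example
(\[100, 20, 18, 17\] → k = 2) and three-component recovery (→ k = 3). A
flat all-zero curve returns the smallest candidate.

**Canonical labels.** Mixture components are relabeled by attenuation:
label 1 = highest mean, label 2 = lowest, labels 3..k = remaining in
descending order. This pins the semantics of named features such as
`MSI_border_proportion_2_3` regardless of EM component ordering, and is
invariant to permutations of the fitted components (tested). The fitted
model serializes to versioned JSON and applies unchanged to validation and
test lesions.

## The MSI matrix and its features

For a label map with k subregions plus background 0, every unordered pair
of neighboring voxels (6-connectivity by default; 26 behind a flag) with at
least one voxel in-mask increments N(label_a, label_b). Pairs wholly in
background are excluded, so N(0,0) = 0 and the matrix describes the lesion
plus its immediate interface rather than the surrounding lung. Counts are
voxel-pair counts on the label-map grid, not spacing-weighted surface
areas. An independent brute-force per-voxel oracle verifies the counts
exactly on random volumes.

With B = Σ_{i<j} N(i,j) (total inter-region border count) and V_i the
in-mask voxel count of label i, the 33 first-order features are: 3 volume
proportions, the background interface fraction, 6 border proportions
N(i,j)/B, 12 conditional border proportions N(i,j)/Σ_{j'≠i}N(i,j'), 4
region boundary shares, 3 interior ratios, the present-pair count, the
pair entropy, and the max/min volume proportion. All ratios follow a
0/0 = 0 convention with per-feature degeneracy flags — a lesion without
subregion 2 simply reports zero for its border features, which is itself
informative (the study population has a median subregion-2 share of zero
in high-grade tumors). The 5 second-order features are the classical
co-occurrence statistics (contrast, correlation, energy, homogeneity,
entropy) on P = N/ΣN with integer labels 0..k as gray levels; a degenerate
marginal defines correlation as 0, flagged. The exact membership of the
first-order list beyond the named border/volume features is the package's
canonical enumeration engineered to the published counts (33 + 5).

## Modeling harness

* **SMOTE** (`smote_resample`): each minority case spawns
  `floor(perc.over/100)` synthetic cases by convex interpolation toward one
  of its k = 5 nearest minority neighbors; the majority class is
  down-sampled to `round(perc.under/100 × n_synthetic)`. Defaults 200/155.
  Two software traditions read these percentages differently; the
  convention used here is documented by the worked example 32 minority →
  64 synthetic → 99 majority kept, which the tests pin down.
* **Leakage guards**: SMOTE, Z-score, preprocessors and feature selection
  all carry a cohort tag and refuse to fit on anything but `"training"`.
* **Selection**: RFE with ridge-logistic importance eliminates one feature
  per step down to `rfe_keep` (default 30; exact duplicate columns are
  collapsed first, first occurrence wins), then an L1 logistic path with
  10-fold CV picks the penalty at minimal CV deviance; if everything
  shrinks to zero the largest penalty with a nonzero path is used and
  flagged.
* **Grid**: Box-Cox (per-feature positivity shift by min + ε), MaxAbs,
  Quantile (empirical CDF to \[0,1\]) and Yeo-Johnson preprocessors ×
  random forest, logistic, QDA, SVM (RBF), decision tree. Preprocessors
  fit on training only; candidates score on validation AUC (ties: higher
  validation accuracy, then grid order); failed fits (e.g. a singular QDA
  covariance) are flagged and ranked last rather than aborting. Classifier
  hyperparameters stay at package defaults under a fixed seed; no inner
  search.
* **Operating threshold**: Youden's J on training predictions. The source
  study reports a 0.525 cut-point without derivation; Youden-on-training is
  this package's declared substitute, not a reconstruction.
* **Evaluation**: AUC with DeLong variance CIs (the AUC itself is the
  tied-rank-sum statistic, bit-identical to all-pairs concordance
  counting); paired DeLong tests (p-values reported raw, uncorrected);
  Wilson CIs for proportions; Brier score with quantile-binned calibration;
  net benefit TP/n − FP/n·pt/(1−pt) with treat-all/treat-none references;
  exact interventional Shapley attributions by full subset enumeration
  (d ≤ 15; the efficiency identity is asserted numerically); size
  subgroups ≤20 / >20–30 / >30 mm with flagged-not-errored degenerate
  strata; and the diagnostic-proportion sample-size formula
  n = ⌈Z²P(1−P)/Δ²⌉.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
with every default fixed once from the published population description:

* **Components**: dense −72.6 ± 60 HU, air-like −827.25 ± 95 HU,
  intermediate −424.05 ± 85 HU (means from the study; the within-component
  standard deviations are the package's realism choice, wide enough that
  raw voxels overlap and habitat recovery is non-trivial, narrow enough
  that supervoxel means cluster). Background lung sits at −850 ± 30 HU.
* **Composition per grade**: low grade 0.20/0.15/0.65, high grade
  0.62/0.03/0.35 (dense/air-like/intermediate), anchored to the published
  per-grade exemplars and medians (high-grade subregion-1 medians
  0.667/0.426/0.776 across cohorts; subregion-2 median 0). Per-case
  fractions jitter log-normally (sd 0.4) and renormalize, giving realistic
  overlap between grades.
* **Geometry**: lesions are mildly eccentric ellipsoids with a smooth
  random surface perturbation, kept single-6-connected. Components are
  placed by thresholding Gaussian-smoothed random fields (filter width =
  `interface_scale`, default 4 mm — a free choice; the study reports no
  interface statistics) at the exact target fractions, producing coherent
  blobs rather than salt-and-pepper noise. In high-grade recipes the
  air-like score gains a radial term (peripheral placement) and the dense
  score a central term, reproducing the reported direction for the
  subregion 2–3 interface (smaller in high grade).
* **Covariates**: drawn per grade from the pooled marginal frequencies of
  the study's baseline table (gender, smoking, attenuation category,
  lobulation, spiculation, …; diameters log-normal around the per-grade
  medians). Covariate correlations are not modeled — only marginals are
  published.
* **Cohorts**: 161/66/128 with 18.6% prevalence (expected high-grade count
  `round(prev × n)` per cohort, totaling 66/355). All randomness descends
  from one master seed through named child streams, so any module can be
  regenerated independently and byte-identically.

**What passing tests do and do not show.** The synthetic cohort has truly
Gaussian component intensities, exactly three components, no scanner or
reconstruction effects, no segmentation error, and covariates independent
of the image content given grade. Success here demonstrates that the
pipeline is correct and self-consistent (it recovers the structure it was
promised, in the right direction, with leak-free bookkeeping) — not that
the model generalizes to clinical CT. On this well-separated cohort the
grade model's AUC approaches 1.0, higher than the 0.8 reported on real
patients; the separation is governed by `fraction_jitter_sd` and the
component fractions if harder problems are wanted.

## Problem sizes and determinism

The test suite runs the full pipeline on the default 355-case cohort once
(about two minutes on one core: supervoxels are compiled, the mixture is
1-D) and keeps module-level fixtures at 8–60 cases. The acceptance script
uses a 60-case cohort for the cluster-count check. Identical seeds
reproduce identical cohorts, fits and manifests; the pipeline caches stage
outputs content-addressed by their configuration, so editing an upstream
key invalidates exactly the downstream stages that consume it (tested).

## Known limitations

* The exact composition of the study's 33 first-order features is not
  public; the canonical enumeration here matches the printed counts and
  the two named features, but individual members may differ.
* Which three second-order features accompany contrast and correlation is
  unstated; energy/homogeneity/entropy are the standard co-occurrence
  choice.
* Whether the study resampled before supervoxel clustering is unstated;
  both paths are supported and the default generator sidesteps the issue
  with isotropic voxels.
* Shapley attributions are exact but exponential in the feature count
  (d ≤ 15); sampling approximations are out of scope.
* Borders are voxel-pair counts, not mm² surface areas; spacing-aware
  weighting is out of scope.
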