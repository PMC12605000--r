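---
title: "Habitat-based MRI radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat-based MRI radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Spinal metastases of EGFR-mutant lung cancer are internally heterogeneous:
a metastatic core of densely packed tumor cells is surrounded by a margin
mixing residual bone, stroma and necrosis. `habitrad` implements a
subregion ("habitat") radiomics pipeline that exploits this spatial
structure to predict a binary molecular label — here the T790M resistance
mutation — from two MRI sequences (a T1-weighted-like and a
T2-fat-suppressed-like volume) with a binary lesion mask per patient.

The pipeline has six stages: (1) entropy-based intratumoral partitioning
into a marginal habitat S1 and an inner habitat S2; (2) radiomic feature
extraction per habitat, sequence and the whole tumor; (3) optional ComBat
scanner harmonization and ICC reproducibility filtering; (4) leakage-safe
feature selection (Mann–Whitney screen, then LASSO-logistic) and
radiomics-signature (RS) construction; (5) a multi-sequence regional
fusion model on the best subregion of each sequence; (6) discrimination,
calibration, decision-curve and Shapley-attribution evaluation.

Because no public cohort with these annotations exists, the package ships
a first-class synthetic cohort generator. Every stage of the pipeline is
validated end to end against the generator's known ground truth and
against independent brute-force oracles.

# Intratumoral partitioning

## Local entropy

For every mask voxel we compute the Shannon entropy (bits) of the
intensity histogram in a 9×9 in-plane window, stride 1, with `B = 32`
equal-width bins over the ROI's min–max range. Two choices deserve
comment:

* **Windows are 2-D, per slice.** Slice spacing is 4 mm against 1 mm
  in-plane; a 3-D window would be severely anisotropic, so neighborhoods
  are in-plane.
* **Windows are clipped to the mask.** Background voxels (outside the
  delineated lesion) never enter the histogram, so entropy near the lesion
  boundary reflects lesion texture, not the mask edge. The bin count is
  not prescribed by the upstream description of the method; 32 bins is the
  package default and is configurable.

Both the entropy map and the raw intensity are Z-scored within each ROI;
the pair (Z-intensity, Z-entropy) is the 2-D feature space for all
subsequent clustering. The "Euclidean distance" of the method is the
metric *in this feature space*, not a spatial coordinate.

## Superpixels and population clustering

Each lesion is clustered into `M = 30` superpixels by k-means on the
per-voxel 2-D vectors. Base R's Hartigan–Wong k-means with 10 random
restarts under a fixed seed stands in for k-means++; the restarts serve
the same purpose (avoiding poor local optima) and the seed makes the
result reproducible. A lesion with fewer than 30 voxels reduces `M` with
a warning; a lesion with exactly `M` voxels makes every voxel its own
superpixel.

Superpixel summaries (mean Z-intensity, mean Z-entropy) from the
*training split only* are pooled and clustered by agglomerative Ward
linkage. For each candidate `K` in 2..10 we compute the Calinski–Harabasz
index and the mean Silhouette; `K*` maximizes the mean Silhouette with
ties broken by higher CH. The two indices usually agree at `K = 2` on
two-habitat data; the combination rule is ours, since only the two
indices themselves are prescribed.

Validation, internal and external patients receive habitat labels by
nearest population centroid — no refitting, hence no leakage. Each
sequence is partitioned independently; habitats are matched across
sequences by the entropy-ordering rule below.

## Naming and the S1/S2 contract

Within each patient, nonempty habitats are renamed in increasing order of
realized mean Z-entropy, so S2 is always the rougher, brighter inner
habitat and S1 the smoother marginal one. Renaming at the patient level
(rather than only at the centroid level) makes the invariant
`mean entropy(S2) >= mean entropy(S1)` hold for every patient exactly,
including borderline patients whose realized means would otherwise invert
the centroid ordering. Population-level identity is preserved in practice
because the centroids are well separated.

# The synthetic cohort generator

The generator emulates the data structure the pipeline assumes:

* **Geometry.** Each lesion is an ellipsoid (default grid 40×40×3 voxels,
  1×1×4 mm spacing) with a concentric inner habitat occupying ~30% of the
  lesion. The through-plane radius is large, so edge slices keep most of
  the equatorial radius — without this, edge-slice rims are swallowed by
  the boundary ring described below. A `scattered` mode places the inner
  habitat as random blobs for robustness tests.
* **Texture.** Both habitats are spatially correlated Gaussian fields.
  The marginal habitat has correlation length 3 voxels (smooth, low local
  entropy); the inner habitat's correlation length shrinks as
  `3 / (1 + entropy_contrast)` and its amplitude grows as
  `1 + entropy_contrast / 3`, so the realized entropy gap increases
  monotonically with `entropy_contrast` (a property test asserts rank
  correlation 1 over {0, 0.5, 1, 2}).
* **Intensity.** The inner habitat's mean exceeds the marginal one's by
  `habitat_contrast` (default 3) noise-SD units, scaled per sequence; the
  two sequences share geometry and class effects but have independent
  noise.
* **Class effect.** Label-positive patients get a rougher, louder inner
  habitat only (`class_effect`, default 0.3, multiplies the inner
  roughness and amplitude). The marginal habitat is untouched, so the
  class signal "lives" in S2 by construction.
* **Batch effects.** Per-scanner additive shift and multiplicative scale
  applied to the final image, *after* class effects — exactly the
  location-scale family ComBat removes. By default (`batch_mode =
  "by_center"`) the external split is the second scanner, mirroring a
  two-center design; note that a leakage-safe train-only ComBat fit then
  sees a single batch and is the identity — the same structural bind a
  real two-center study faces (and consistent with falling back to ICC
  filtering instead of harmonization). An `"interleaved"` mode alternates
  scanners across all splits so the harmonization path can be exercised
  meaningfully. Per-ROI Z-normalization during preprocessing already
  absorbs most *image-level* location-scale scanner effects; ComBat's
  real work is feature-level batch structure, which the module tests
  plant directly.
* **Clinical table.** Age, gender, smoking (correlated with the label,
  odds mirroring a typical training cohort), performance status, and
  log-normal CEA/CYFRA/NSE markers; splits are assigned 2:1
  train:internal (stratified by label) within the first scanner.

**Why these defaults.** The defaults were chosen once, as the study
conditions for the whole test suite, to produce *clearly* two-modal
lesions: the 9×9 entropy window inevitably blurs a ~4-voxel boundary ring
around the inner habitat, and if the rim is thin or the contrasts weak,
that ring forms a third cluster in feature space that destabilizes the
Silhouette selection of `K`. A 40-voxel grid, inner fraction 0.3,
3-SD intensity contrast and 1.5 entropy contrast keep the ring a small
minority of voxels, which is what "two spatially organized habitats"
should mean for a testbed. What the generator does **not** emulate:
realistic bone anatomy, pulse-sequence physics, partial-volume effects,
inter-reader segmentation variability (approximated only by the 1-voxel
mask jitter), or correlated multi-lesion patients. Passing tests
demonstrate the pipeline's internal correctness and its ability to
recover planted structure; they say nothing about discrimination on real
lesions.

# Features

Texture matrices (GLCM, GLDM, GLSZM, GLRLM, NGTDM) are computed in 3-D
with distance-1, 26-connectivity offsets and angle averaging, matching
the "3D" tokens in the reference feature names; an in-plane 2-D mode
exists. Intensities are discretized to a fixed bin count (default 32,
equal-width over the region's range) at feature time. The implemented
set covers the six headline features — GLDM
DependenceNonUniformityNormalized, GLCM InverseVariance, GLCM MCC, GLSZM
SmallAreaEmphasis, first-order 90th percentile (type-7 linear
interpolation, pinned because the value depends on the convention) — plus
one representative of each remaining family (GLRLM ShortRunEmphasis,
NGTDM Coarseness) and basic first-order statistics. Reproducing a
1,967-column catalogue is a non-goal; every implemented feature is
oracle-tested against brute-force enumeration and an independent numpy
reference implementation.

Image filters: square, square root, logarithm, exponential (monotone
range-preserving maps), gradient magnitude, scale-normalized Laplacian of
Gaussian (`sigma` in mm, converted through the voxel spacing; default
sigmas 3 and 5 where a list is needed), undecimated single-level Haar
wavelet subbands (HHH by default), and 2-D rotation-invariant uniform LBP
per slice. The upstream description lists a 2-D LBP while the reference
feature names say `lbp-3D-m2`; we implement the honest 2-D filter and
emit its features under `lbp-2D` by default, with `lbp_name = "lbp-3D-m2"`
available for naming parity (the discrepancy is logged in the schema).
Shape features are deliberately absent: subregion shape is a clustering
artifact, and no headline feature is a shape feature.

The ICC reproducibility filter emulates a second reader by 1-voxel
morphological mask jitter (half of the boundary toggled, seeded), then
computes ICC(A,1) — two-way mixed effects, absolute agreement, single
measures — per feature *within each sequence × region*, retaining
features with ICC > 0.80. Region-wise ICC matters: a feature can be
stable in the inner habitat yet boundary-sensitive in the rim, and
pooling rows across regions would wrongly discard it everywhere.

# Harmonization

`fit_combat()`/`apply_combat()` implement parametric empirical-Bayes
ComBat with a strict train-fit/apply split: location-scale batch
parameters are estimated on training rows (standardization against the
batch-size-weighted grand mean and pooled variance; EB shrinkage of batch
means toward a normal prior and batch variances toward an inverse-gamma
prior, both estimated across features within batch) and applied frozen to
validation rows. Unknown batch ids error out rather than passing through.
Two non-standard choices:

* **Population variance divisor.** Per-batch scale uses the `n` (not
  `n-1`) divisor, which makes refit-on-harmonized-data an exact identity
  for the shrinkage-free path — a useful audit — at an O(1/n) difference
  from the reference implementation (agreement with `sva::ComBat` is
  cross-checked in the tests).
* **Confounded designs.** When batch and a covariate are collinear (e.g.
  batch 100% confounded with the label) the joint model cannot split the
  shared variation; we attribute it to the covariate (covariate-first
  fit, batch effects on residuals) with a warning, protecting the
  biological signal where the reference implementation simply refuses.

Both the harmonized and unharmonized paths are first-class: the
evaluation default is the unharmonized path (multistep preprocessing +
ICC filtering), with ComBat available by configuration, and the run
directory records which path ran.

# Signatures, fusion and leakage control

Per region × sequence: features are standardized with training-split
mean/SD (frozen for validation), screened by a two-sided Mann–Whitney U
test at `P < 0.05` (no multiplicity correction by default, mirroring the
plain screen; a BH-FDR switch exists), then passed to an L1-penalized
logistic regression (`glmnet`), with the penalty chosen by 5-fold inner
cross-validated binomial deviance (`lambda.min`; `lambda.1se` is a
configuration option). The radiomics score is the weighted linear
combination of selected features; a logistic layer maps RS to
probability, and the training Youden cutoff is stored and frozen for all
validation splits (per-split refitting is available but off by default).

`run_nested_cv()` wraps screening + LASSO + the logistic layer in outer
stratified 5-fold cross-validation over the training split only: pooled
outer-fold predictions give an honest performance estimate, and the final
deployment model is refit on the full training split. A fold whose screen
retains nothing contributes the training prevalence as its prediction —
the honest null forecast — rather than aborting. Internal and external
splits are never touched before evaluation.

The fusion model is a logistic regression on the two parent RS scores
(best subregion per sequence, chosen by training AUC; on these synthetic
cohorts that is S2 for both sequences by construction). Collinear or
separated parents fall back to a tiny ridge (`lambda = 1e-6`). A
combined whole-tumor model (fusion of the two whole-region signatures) is
fitted for comparison.

# Evaluation

AUC uses the Mann–Whitney pair-counting identity with ties at 1/2;
confidence intervals and the paired model comparison use the DeLong
placement-value covariance (a 2000-replicate simulation keeps the type-I
error within [0.03, 0.07] at the 5% level). AUPRC is the step-interpolated
precision–recall area with a seeded percentile bootstrap CI. Decision
curves report `NB(pt) = TP/N − (FP/N)·pt/(1−pt)` on a 0.01–0.60 grid
against treat-all/treat-none; calibration uses 5 quantile bins plus
logistic recalibration intercept (offset model) and slope. Cohort tables
use Mann–Whitney for continuous and chi-square (Yates for 2×2, Fisher
fallback when an expected cell is below 1) for categorical covariates.
All metrics are invariant under patient reordering, and AUC under
monotone score transforms (both property-tested).

# Attributions

On the logit scale every fitted model here — RS and fusion alike — is
linear in its (standardized) features, so the Shapley value with mean
imputation has the closed form `phi_f(x) = w_f (x_f − mean_bg(x_f))`,
with the training split as background. Local accuracy
(`sum(phi) + base = margin`) is exact, and tests verify equality with
full coalition enumeration for small models. For the fusion model the
chain rule through the fusion coefficients is also exact — the
composition of linear maps is linear — so the two-level report
(attributions over the two parent RS inputs, and over the underlying
features) involves no approximation.

# Numerical choices and degenerate inputs

* Constant regions: entropy 0; GLCM IV 0; MCC undefined (error, row
  dropped with a logged reason); GLSZM single zone; NGTDM coarseness
  capped at 1e6.
* Discretization always yields levels exactly 1..`n_bins`; the maximum
  intensity maps to the top bin.
* Youden ties break toward higher specificity; cutoffs are midpoints of
  adjacent distinct scores with outer sentinels.
* DeLong degeneracy (identical score vectors) returns `p = 1` with a
  flag.
* k-means that cannot produce `M` nonempty superpixels retries with new
  restarts before erroring.
* Empty habitats are allowed per patient; feature rows below a 10-voxel
  floor are dropped and logged. Under weak signal the rim (S1) or
  whole-tumor screen can legitimately retain fewer than 2 features; the
  model grid then records an explicit failure reason for that entry
  rather than silently shrinking.

# Problem sizes used by the shipped analyses

The analysis scripts run a 110-patient cohort (80 scanner-1 patients
split 2:1 train:internal, 30 scanner-2 patients as the external split,
prevalence 50/110) with the full filter set. The test suite and the
acceptance script use smaller cohorts (8–60 patients, 1–3 filters) and
between 5 and 20 replicate seeds per property; these sizes were chosen
once as the smallest that leave the tested contrasts comfortably
detectable — in particular, the inner-habitat dominance check uses
60-patient all-training cohorts because at half that size the screening
stage is underpowered and the ordering becomes undefined rather than
wrong. Sizes are stated alongside each reported number.

# Known limitations

* The generator's habitats are (by default) concentric and sharply
  bounded; real habitat boundaries are gradual and the marginal habitat
  is anatomically heterogeneous.
* The 9×9 entropy window imposes a resolution floor: habitats thinner
  than ~5 voxels cannot be recovered reliably, by any parameterization.
* Only two sequences and a single fusion layer are supported; >2-sequence
  fusion, SLIC-style spatial superpixels and spatially regularized
  clustering are out of scope.
* Absolute performance numbers on synthetic cohorts are not comparable to
  any real-data study; only orderings and internal-consistency properties
  are meaningful.
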