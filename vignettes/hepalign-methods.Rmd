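---
title: "Mask-driven affine registration of longitudinal liver images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-driven affine registration of longitudinal liver images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepalign)
```

## The problem

Longitudinal surveillance of focal liver observations compares a baseline
hepatobiliary-phase (HBP) series against a follow-up acquired months later.
Between the two acquisitions the liver moves (respiratory displacement on
the scale of tens of millimetres), the field of view shifts, voxel sizes
differ, and contrast uptake varies. Radiologists compensate manually by
scrolling to a matching slice and mentally re-orienting; that protocol is
slow and imprecise. `hepalign` implements a fully automated two-step
alternative:

1. **Segment** the liver on each series to obtain binary masks (any
   segmenter can stand behind this step — see below).
2. **Register** the masks with a 12-parameter affine transform, then apply
   that transform to the whole moving series, not just the mask.

Driving the optimization with masks rather than raw intensities makes the
method indifferent to intensity differences between series — uptake
variation, bias fields, bright structures outside the liver, even a change
of modality — because everything outside the organ is literally zero.

## The transform model

The transform has 12 degrees of freedom: translation $t \in \mathbb{R}^3$
(mm), rotation $r \in \mathbb{R}^3$ (radians), scale
$s \in \mathbb{R}_{>0}^3$ and shear $h \in \mathbb{R}^3$. The matrix is
composed as

$$ M\,x = t + c + R_z R_y R_x \, H \, S \,(x - c), $$

where $c$ is the rotation centre and $H$ is upper-triangular with unit
diagonal and entries $(h_{xy}, h_{xz}, h_{yz})$. Centring the linear part
on the static liver-mask centroid decouples rotation and scale from
translation, which stabilizes optimization; with no mask available the
volume centre is used. The determinant of the linear block is exactly
$s_x s_y s_z$: rotations and shears are volume-preserving.

Matrices follow the **pull-back convention**: $M$ maps static-space
physical coordinates (mm) into moving space, which is exactly what
resampling consumes — the value of the registered image at $x$ is the
moving image sampled at $Mx$. A feature at $p_m$ in the moving series
therefore appears at $M^{-1}p_m$ after registration, and landmark code
uses the inverse. All geometry lives in physical millimetres, never voxel
indices, so anisotropic and mismatched voxel grids are handled uniformly.

## Optimization

`register()` minimizes a similarity loss by Adam gradient descent with
central finite-difference gradients (12 parameters, hence 24 extra loss
evaluations per iteration) over a multi-resolution pyramid. Defaults:

* **Loss**: negative soft Dice, $1 - 2\sum ab / (\sum a^2 + \sum b^2 +
  10^{-7})$, for binary masks — the natural differentiable surrogate of
  the Jaccard score used for evaluation. Mean squared error after per-image
  min-max normalization for intensity inputs; negative Pearson correlation
  is also available.
* **Working grid**: both inputs are resampled to an isotropic working grid
  before optimization; the final matrix is expressed in mm, so it applies
  exactly on the native grids. The default working spacing is 1.5 mm. A
  coarser grid (e.g. 2 mm) halves the cost but leaves the optimizer unable
  to settle the half-voxel quantization inherent in nearest-neighbour mask
  resampling, which caps achievable overlap well below what the data
  support; at 1.5 mm a purely translated mask is recovered to its exact
  quantized optimum.
* **Pyramid**: factors 4, 2, 1 with Gaussian smoothing (sigma = factor/2
  voxels) before each downsampling; masks become soft at coarse levels and
  are used soft in the loss, which keeps gradients informative. The
  capture range comfortably covers 30 mm respiratory-scale shifts.
* **Parameter schedule**: shear is frozen at the coarsest levels. Heavily
  smoothed organ masks are close to ellipsoids, and an ellipsoid is mapped
  onto itself by a continuum of rotation-shear-scale combinations; fitting
  shear only at the finer levels removes that degeneracy. This mattered in
  practice: without it, occasional pairs converged to a large spurious
  rotation compensated by shear.
* **Learning rates**: per parameter group (1.0 mm translation, 0.01 rad
  rotation, 0.005 scale and shear), because a useful step in millimetres
  is orders of magnitude larger than a useful step in radians.
* **Iterations**: 100/120/25 per level, with an early stop when the
  relative loss change over 10 iterations falls below $10^{-5}$.
* **Initialization**: identity, except the translation is set to the
  difference of the mask centroids. Whole-image mode starts at plain
  identity. At the finest level the initialization is re-evaluated and
  kept if it beats the optimized parameters — a guard that makes
  self-registration exactly stable and caps the damage of any coarse-level
  misstep.
* **Restricted variants**: `enabled_params` freezes any subset of the 12
  parameters at their initial values; `tie_scale` reduces the three scales
  to one isotropic factor. Rigid, z-only and the manual-emulation protocol
  are all expressed through this one mechanism.

The default path contains no randomness: gradients, initialization and
stopping are deterministic, so identical inputs and configuration
reproduce bit-identical transforms. The seed argument is threaded through
and recorded for provenance (and for optional random restarts, off by
default).

## Segmentation

The registration contribution consumes masks, not a specific segmenter,
so the segmenter is pluggable: `kind = "file"` accepts any precomputed
mask (e.g. from a trained CNN) unchanged, and `kind = "threshold"` is a
classical fallback — a fixed or automatic threshold (maximal
between-class variance on a 256-bin histogram) followed by the standard
morphology for organ masks: largest 26-connected component, internal
hole filling, then morphological closing (default radius 1 voxel). The
post-processing is idempotent. The intensity-mask input is the voxelwise
product of mask and original image: organ intensities inside, zero
outside.

## Evaluation metrics

Three metrics, computed per pair:

* **Liver overlap score**: Jaccard index of the static mask and the
  registered moving mask (nearest-neighbour resampling keeps it binary);
  1 is perfect overlap.
* **Image correlation**: mutual information of the static and registered
  moving intensity masks, from a joint histogram with 64 equal-width bins
  per image spanning each image's own range, in nats (a bits option
  exists). Because MI depends on each pair's intensity distribution it is
  used for paired comparisons only, never across datasets. Background
  zeros are included by default, matching the intensity-mask definition;
  a flag excludes them.
* **Intra-observation distance**: for each observation label shared
  between the series, $\lVert p_\text{static} - M^{-1} p_\text{moving}
  \rVert$ in mm; 0 is perfect co-localization. Matching is by label,
  never nearest-neighbour.

Cohort arms are compared with two-sided paired t-tests, a Bonferroni
multiplier equal to the number of comparisons, and analytic 95%
confidence intervals; zero-variance differences are flagged as exactly
equal rather than producing NaN.

## The manual-registration emulator

The comparator mimics the radiologists' protocol: first align the slice
showing an internal landmark in both series (a pure z-shift from slice
arithmetic; an exhaustive slice-overlap search is the fallback when no
landmark slices are given), then apply a rigid correction — translation,
rotation and one isotropic scale, shear frozen at exactly zero — found by
the same optimizer over the restricted parameter set. Running the
correction as an optimization is deliberately the most favourable
realizable reading of a human rigid alignment, so comparisons against the
full affine method are conservative. Whether a human "scaling" is
isotropic is ambiguous; isotropic was chosen and is asserted by tests.

## The phantom generator

Synthetic pairs stand in for clinical data and carry exact ground truth:

* **Anatomy**: the liver is a smoothed union of 2–4 overlapping
  ellipsoids (an asymmetric blob of realistic ~0.5–1 L scale on the
  default 120 × 120 × 84 mm field of view at 1.5 mm isotropic voxels);
  a dark 3 mm-radius vessel runs through it, and its central slice is the
  designated landmark slice (the phantom's analogue of the portal-vein
  slice a reader would pick). Dark spherical nodules (default radii
  2–10 mm) stand in for focal observations; their centres are the
  landmark set.
* **Intensities**: bright parenchyma (mean 100, texture SD 5) over dark
  background (mean 10), HBP-like; a global uptake-scale factor emulates
  suboptimal contrast uptake; Gaussian noise (SD 5) is drawn
  independently for the two series of a pair so registration cannot
  exploit shared noise; an optional low-order polynomial bias field and
  an independently placed bright background distractor provide intensity
  confounds that leave masks untouched.
* **Ground truth**: the moving series is the noise-free anatomy resampled
  through the inverse of a known affine; landmarks are mapped
  analytically through the matrix, never through image resampling, so
  metric ground truth is exact to machine precision. A perturbation that
  would clip more than 20% of the liver volume out of view is refused as
  unrealistic.
* **Cohorts**: difficulty presets set the perturbation ranges — easy
  (|t| ≤ 5 mm, |r| ≤ 3°), moderate (|t| ≤ 15 mm, |r| ≤ 10°, scale
  0.9–1.1, |shear| ≤ 0.1; the respiratory-displacement scale), hard
  (adds voxel-spacing mismatch and uptake scale 0.5). Everything derives
  from one seed; written cohorts reproduce file-for-file.

What the phantom does **not** emulate: nonlinear (biomechanical) liver
deformation, MRI physics (coil profiles beyond the polynomial bias,
motion artifacts), oblique acquisitions, and anatomy beyond one organ,
one vessel and a few nodules. Passing tests on phantoms therefore
demonstrate that the estimator recovers transforms within the affine
family it models, that mask-driven registration is robust to intensity
confounds where whole-image registration is not, and that the rigid
manual emulation is strictly weaker when the truth contains shear — they
do not certify clinical segmentation quality or accuracy under real
deformation.

## Numerical choices and degenerate inputs

* Interpolation is linear for intensities and nearest for masks
  (preserving binarity), with fill value 0 (background in both mask and
  magnitude images) for out-of-field samples.
* Mask-grid quantization: a nearest-resampled mask moves by whole voxels,
  so a recovered translation legitimately differs from the continuous
  truth by up to half a voxel per axis. Tests assert recovery within
  1 mm per axis at 1.5 mm voxels.
* Empty masks are an error state everywhere (an all-background
  segmentation cannot drive registration); constant volumes cannot be
  thresholded; a constant image has zero entropy and yields MI 0 rather
  than an error; Jaccard of two empty masks is undefined and raised as an
  error.
* Singular matrices are refused on construction and inversion
  (|det| < 1e-12).
* Scale parameters are clamped to at least 0.05 during optimization to
  keep the matrix invertible along the search path.
* Volumes are assumed axis-aligned with positive axis directions; NIfTI
  files with oblique or flipped orientation matrices are rejected
  explicitly rather than silently reinterpreted.

## Problem sizes used by the test suite

The packaged studies use 20-pair moderate-difficulty cohorts on the
default 80 × 80 × 56 phantom grid — large enough for stable cohort means
and sub-voxel recovery, small enough that the full suite runs on a
laptop-class single core in minutes. Unit tests use a 48 × 48 × 40 grid
at 2 mm where geometric detail is irrelevant.

## A worked example

```{r example, eval = FALSE}
ph <- make_phantom(phantom_spec(seed = 7))
pair <- perturb_pair(ph, affine_params(translation = c(8, -5, 4)),
                     noise_seed = 11)
reg <- register(pair$static$mask, pair$moving$mask,
                registration_config(mode = "binary_mask"))
reg$params$translation
#> [1]  7.5 -4.5  4.5         # the quantized optimum: 5, -3, 3 voxels
pair_metrics(pair$static$mask, pair$moving$mask, reg$matrix,
             static_lms = pair$static$landmarks,
             moving_lms = pair$moving$landmarks)[c("jaccard",
                                                   "mean_landmark_distance")]
#> $jaccard                  [1] 1
#> $mean_landmark_distance   [1] 0.866
```

## Known limitations

* The affine family cannot express local deformation; this is by design
  (affine is preferred for diagnostic overlay because it cannot fabricate
  or destroy focal structure), but residual landmark error on strongly
  deformed anatomy is expected.
* The threshold segmenter is a fallback for phantoms and well-contrasted
  volumes, not a clinical liver segmenter; real pipelines should supply
  masks from a dedicated model via `kind = "file"`.
* Finite-difference gradients cost 2 evaluations per active parameter per
  iteration; an analytic-gradient backend would cut runtime roughly an
  order of magnitude without changing results.
* Mutual information is reported on the common grid of the pair including
  background zeros by default; with very small livers the background
  bin dominates both marginals and compresses MI differences.
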