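# hepalign

Fully automated affine registration of longitudinal 3D liver images,
driven by segmentation masks.

## The problem

Comparing a baseline hepatobiliary-phase (HBP) liver MRI against a
follow-up means compensating for respiratory displacement (tens of mm),
field-of-view shifts, voxel-size mismatch and contrast-uptake variation.
Radiologists do this by scrolling to a matching slice and mentally
re-orienting — slow and imprecise. `hepalign` automates it in two steps:

1. **Segment** the liver on each series into a binary mask (a pluggable
   step: any segmentation model's mask can be supplied, with a classical
   threshold + morphology fallback built in).
2. **Register** the masks with a 12-parameter affine transform
   — translation *t* (mm), rotation *r* (rad), scale *s*, shear *h*,
   composed as `M x = t + c + Rz·Ry·Rx · H · S · (x − c)` about the
   static liver centroid *c* — then apply `M` to the **whole** moving
   series, not just the mask.

Because everything outside the liver is zero in the mask, the
optimization is indifferent to intensity confounds (uptake differences,
bias fields, bright extrahepatic structures), which is exactly where
whole-image registration fails. Optimization is Adam gradient descent
with finite-difference gradients on a negative-soft-Dice loss
(`1 − 2Σab/(Σa² + Σb² + ε)`), over a coarse-to-fine pyramid in physical
millimetres.

The package also ships the three standard evaluation metrics — liver
overlap score (Jaccard index), image correlation (mutual information,
nats) and 3D intra-observation distance (mm between matched observation
centres) — an emulator of the manual slice-landmark + rigid protocol for
comparison studies, and a synthetic liver phantom generator with exact
affine ground truth so the whole pipeline is testable without clinical
data.

## Worked example

```r
library(hepalign)

# a synthetic HBP-like liver with known ground truth
ph   <- make_phantom(phantom_spec(seed = 7))
pair <- perturb_pair(ph, affine_params(translation = c(8, -5, 4)),
                     noise_seed = 11)

reg <- register(pair$static$mask, pair$moving$mask,
                registration_config(mode = "binary_mask"))
reg$params$translation
#> [1]  7.5 -4.5  4.5

pair_metrics(pair$static$mask, pair$moving$mask, reg$matrix,
             static_lms = pair$static$landmarks,
             moving_lms = pair$moving$landmarks)[
  c("jaccard", "mean_landmark_distance")]
#> $jaccard
#> [1] 1
#> $mean_landmark_distance
#> [1] 0.8660254
```

The recovered translation is the exact quantized optimum: the moving
mask, resampled on a 1.5 mm grid, sits at (5, −3, 3) whole voxels =
(7.5, −4.5, 4.5) mm, so post-registration liver overlap is perfect
(Jaccard 1.0) and the mean observation co-localization error is 0.87 mm
— the half-voxel quantization, not optimizer error.

Cohort studies compare registration arms with paired statistics:

```r
cohort <- generate_cohort(20, "moderate", seed = 101)
ev <- evaluate_cohort(cohort, arms = c("binary_mask", "baseline"))
ev            # per-arm mean +/- SD of all three metrics
ev$comparisons$jaccard_binary_mask_vs_baseline
```

A command-line front end is installed with the package
(`system.file("cli", "hepalign", package = "hepalign")`) with
subcommands `register`, `segment`, `simulate`, `evaluate`, `baseline`.

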