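---
title: "Harmonizing smartphone fundus images and cost-weighted plus-disease classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing smartphone fundus images and cost-weighted plus-disease classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Retinopathy of prematurity (ROP) is a retinal vascular disease of preterm
infants and the leading preventable cause of infantile blindness. Its
treatment trigger is *plus disease*: marked dilation and tortuosity of the
posterior retinal vessels. In low-resource settings, screening increasingly
relies on fundus photographs taken through an inexpensive condensing lens
with a smartphone. These images are small (300–1200 px a side), variably
lit, sometimes contaminated by specular reflections, and show the fundus as
a bright disc on a black background.

`fundusplus` implements the complete screening workflow around two ideas:

1. **Harmonization** — a deterministic enhancement pipeline that puts every
   image, whatever its source, on a common 800×800 high-vessel-contrast
   footing.
2. **Cost-weighted learning** — a binary classifier trained with a
   *real-world-weight cross-entropy* (RWWCE) in which the two error
   directions carry their estimated dollar costs, so that a missed case of
   plus disease (lifelong blindness, priced at $1,700,000) weighs 100 times
   an unnecessary treatment ($17,000).

Because clinical images cannot be redistributed, the package ships a
synthetic preterm-retina generator with the same statistical structure, so
every stage is exercised end to end by the test suite.

## The harmonization pipeline

`harmonize()` composes, in order and at native resolution:

1. `extract_green()` — the green channel, which carries the highest
   vessel-to-fundus contrast in RGB fundus photographs.
2. `detect_fundus_circle()` — a Hough circular transform. Pixels with
   gradient magnitude above the `hough_edge_quantile` (default 0.90) vote
   for circle centers at every radius in `hough_radius_frac` (default
   0.30–0.60 of the shorter side) along ± the local gradient direction. The
   sweep runs on a copy downsampled to ~192 px, the peak of a 3×3
   box-summed accumulator is taken, and the circle is refined at full
   resolution by maximizing mean gradient magnitude along its perimeter. A
   peak weaker than `hough_min_score` (0.20 of the perimeter) falls back to
   a full-frame mask with a warning — a *distinguishable* outcome recorded
   in the provenance.
3. `crop_and_square()` — multiply by the mask, crop to its bounding box,
   pad with zero rows/columns symmetrically (extra pixel bottom/right).
4. `unsharp()` — linear unsharp masking
   `out = clip(in + gain · (in − boxmean(in)))` with a 5×5 averaging filter
   and gain 3. The source recipe says only "averaging filter with a gain of
   3"; we read the gain as multiplying the high-pass term (the common
   formulation) rather than as a (1+g) blend — a documented choice, not an
   established fact.
5. `clahe()` — contrast limited adaptive histogram equalization, 8×8 tile
   grid, relative clip limit 0.01 (counts clipped at `clip · tile_area`,
   excess redistributed uniformly), bilinear interpolation between tile
   mappings. The original's CLAHE parameters and bit depth are unreported;
   we work in floating point throughout with 256 histogram bins and make
   both knobs configurable.
6. `gaussian_smooth()` — σ = 1 px at pre-resize resolution, counteracting
   over-sharpening of non-vascular structure (e.g. specular edges). σ is
   unreported in the source; 1 px is deliberately mild.
7. `resize_square()` — bilinear resampling to 800×800, *last*, so all
   filtering happens at native scale.

All convolutions use reflective borders (zero padding would ring a dark
halo around the fundus rim). Pixels live on `[0, 1]` as doubles; 8-bit
quantization happens only at file I/O. The pipeline contains no randomness.

Enhancement is quantified by the **contrast improvement index**:
`local_contrast()` sweeps a 3×3 window over every fully interior position
and averages `(max − min)/(max + min)`; `cii()` is the ratio of that
statistic for the processed versus the original image. Two silent corners
are pinned down as package decisions: windows are interior-only (padding
would inject border contrast), and windows with `max + min = 0` contribute
0 instead of being dropped. The whole frame is used by default; a `mask`
argument restricts to the fundus if wanted.

## Class imbalance: augmentation and balanced selection

The clinical cohort this package models held 385 "no plus" (including "pre plus", merged by
`merge_preplus()`) against 55 "plus" images. `stratified_kfold()`
partitions each class as evenly as possible over `k` folds, so `k = 5`
yields 308/44 training and 77/11 test images per fold, exactly.
`augment_eightfold()` inflates each image to 8 variants — identity, five
rotations, and the two axis reflections; the rotation angles are
unreported in the source, so we use the maximally spread set
{60°, 120°, 180°, 240°, 300°} (0° being the identity member), configurable.
`balance_select()` then draws an equal number per class (600 total by
default) without replacement.

Two engineering decisions around this:

* Augmentation happens **after** harmonization, so all variants share the
  centered disc-on-black geometry and a zero fill for rotations is exact.
* `augment_dataset()` does not materialize 2464 × 800×800 arrays (~12 GiB);
  it emits provenance rows (`parent_id`, `augmentation`) and the transform
  is applied lazily after the classifier downscales the parent to its
  working resolution. Rotation and bilinear downscaling commute up to
  interpolation error, and the provenance tags double as the leakage
  guard: `train_classifier(test_ids =)` refuses any training row whose
  parent is held out.

## The loss

For a batch of M predictions `h` with binary targets `y`,

```
J = -(1/M) * sum( w_fn * y * log h  +  w_fp * (1 - y) * log(1 - h) )
```

with `h` clamped to `[1e-7, 1 - 1e-7]`. Unit weights recover standard
cross-entropy exactly; scaling both weights scales the loss without moving
its optimum. Because raw dollar weights put the loss at ~10⁶,
`loss_spec(normalize_weights = TRUE)` (default) divides both by `w_fp`,
preserving the 100:1 ratio while keeping optimizer steps sane; raw dollars
remain available. The natural logarithm is used (any base is a uniform
rescale). Whether the original normalized during optimization is
unreported; our default is a package decision justified by the
homogeneity of the loss.

## The classifier

The published model is an ImageNet-pretrained 22-layer inception network
with the first 20 layers frozen and the head replaced. Pretrained weights
and a deep-learning runtime are not available in this environment, so that
backbone survives only as a config value with an informative error, and the
verification surface is the `small_cnn`: four 3×3 conv blocks
(8/16/32/32 channels, ReLU, 2×2 max pooling after the first three), global
average pooling, and a 2-unit softmax head, with im2col convolution and
backpropagation implemented in C++ and verified against finite differences
to 1e-10. Inputs are downscaled from 800×800 to `input_side` (128 default)
inside the model adapter. Optimizer settings (Adam, lr 1e-3, batch 32, 10
epochs) are package defaults — the source reports none.

The global-average-pooling head makes **class activation maps** exact:
`cam()` is the class-weighted sum of the final conv feature maps,
rectified, upsampled, and max-normalized.

## Evaluation

`confusion_counts()` (threshold 0.5 by default), `classification_metrics()`
(undefined ratios are `NA`, never silently 0), `roc_empirical()`
(tie-grouped step curve; trapezoidal AUC equals the Mann–Whitney statistic
with ties at ½), and `roc_binormal()` — the parametric estimate. The
source does not say which parametric ROC model it used; we assume the
binormal model, fitting class-conditional normals (probit-transforming
bounded scores first) with `AUC = Φ((μ₁−μ₀)/√(σ₀²+σ₁²))`.
`real_world_cost()` is `(w_fn·FN + w_fp·FP)/n` dollars per screened
infant. `cohort_projection()` scales the average per-fold false-negative
count to a cohort (default fold denominator 11 = 55 plus cases over 5
folds, reconstructed from the stated stratification), rounding half-up so
that 1000 · 0.125 · 3.3/11 = 37.5 projects to 38 infants; `cost_delta()`
prices the difference. `roc_average()` pools fold-wise ROC curves by
vertical averaging on an FPR grid (the pooling method is likewise
unreported; vertical averaging is the standard choice).

## The synthetic world

`generate_retina()` renders: a fundus disc (radius 0.35–0.48 of the side,
jittered center) on an exactly-zero background; a radial shading profile
with a linear illumination tilt (0–0.25 relative); a bright optic-disc
blob; 6–12 radial vessels whose centerlines are sinusoidally perturbed
with amplitude `tortuosity_amp · path length` (end-pinned), rendered by
darkening green most (−65%), red less (−30%) — reproducing the green
channel's vessel-contrast advantage; and 0–3 saturated specular blobs.
Image sides are drawn uniformly from [300, 1200] px, per image.

Class structure: plus draws have mean tortuosity amplitude 0.045 versus
0.015 and ~1.6× the vessel caliber. The source reports no quantitative
tortuosity/dilation statistics for its classes, so this gap is an explicit
free parameter (`effect_size`, default 1 = clearly separated classes;
0.3 is used in tests as the "overlapping classes" regime). These values
were fixed before the acceptance properties were measured and are not
tuned. The generator returns its own centerlines so the class gap can be
verified with `tortuosity_index()` (arc/chord ≥ 1) rather than trusted.

What the generator does **not** emulate: vascular branching, sensor noise
and compression artifacts, non-square frames, peripheral (non-optic-nerve)
views, and real anatomical texture. A green test on this world therefore
establishes that the *mechanisms* work (enhancement raises measured
contrast; the cost-weighted loss trades false positives for false
negatives; the classifier learns vessel geometry), not that clinical
performance figures (AUC 0.9754, CII 1.899, $65,768.75) are reproduced —
those require the unreleased 440-image dataset and pretrained backbone.

## Numerical choices and degenerate inputs

* Reflection borders everywhere; kernel truncation at 3σ for Gaussians.
* Constant images: CLAHE maps them to a (spatially) constant output; circle
  detection takes the flagged full-frame fallback; `local_contrast` is 0.
* `cii()` with a zero-contrast original raises an undefined-ratio error
  rather than returning infinity.
* Coincident centerline endpoints raise a degenerate-input error.
* All RNG flows through R's generator via `withr::with_seed`; identical
  seeds give bit-identical cohorts, selections and trained networks.
  Derived seeds stay below 2³¹.

## Worked example

```{r example}
library(fundusplus)

cohort <- generate_cohort(n_no_plus = 88, n_plus = 12, seed = 1)
report <- run_pipeline(pipeline_config(
  n_no_plus = 88, n_plus = 12,
  classifier = classifier_config(input_side = 64, epochs = 10),
  loss = loss_spec("rwwce"), seed = 1))
report$metrics
report$auc_empirical

# projected impact of the false-negative reduction reported for the
# cost-weighted loss, on a 1000-infant cohort at 12.5% prevalence
miss_ce <- cohort_projection(1000, 0.125, 11, avg_fn = 3.3)
miss_rw <- cohort_projection(1000, 0.125, 11, avg_fn = 2.65)
cost_delta(miss_ce, miss_rw) # $13,600,000
```

## Known limitations

* The small CNN is a verification-scale stand-in: its absolute accuracy on
  real smartphone images is unknown and untested here.
* Circle detection assumes one dominant circular boundary; montages or
  severely clipped fundi will fall back to the full frame.
* CLAHE on floating data with 256 bins is one of several defensible
  readings of the original pipeline.
* The synthetic world's class separation is assumed, not calibrated.
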