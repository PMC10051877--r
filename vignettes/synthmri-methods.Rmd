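---
title: "Synthetic prostate MRI slices with a single-image GAN and an automated quality gate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic prostate MRI slices with a single-image GAN and an automated quality gate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

synthmri implements a complete desk-scale pipeline for studying synthetic
T2-weighted prostate MRI slices:

1. **phantom** – a parametric generator of prostate-slice-like images with
   contour ground truth, so every later stage is testable without patient
   data;
2. **prep** – intensity normalization, centered square crop/resize and the
   slice-selection rules that produce training inputs;
3. **msgan** – a coarse-to-fine single-image GAN (one generator/critic pair
   per scale of an image pyramid) that synthesizes random variants of one
   training image;
4. **segqc** – a small encoder–decoder prostate segmenter plus the automated
   quality gate (single connected component, minimum area) that screens
   synthetic images;
5. **evalstats** – scoring of blinded rater studies (percent correct, false
   positives/negatives, pairwise concordance) and the associated tests
   (Pearson chi-square, Wilcoxon signed-rank, two-sample t);
6. **classifier** – a stratified splitter and a small CNN used to check that
   synthetic and conventional phantoms behave alike in downstream
   classification and anomaly (lesion) detection.

This vignette records the modelling choices, their rationale, and what the
desk-scale experiments do and do not demonstrate.

## The phantom model

Real axial pelvic MRI is replaced by an ellipse-composite phantom: a dark
background (intensity 0.05), a bright body ellipse (0.35), a mid-intensity
prostate (0.50) with a hyperintense peripheral rim (0.75) occupying the outer
25% of the gland radius, a hyperintense bladder (0.85) above the gland, and
optionally a hypointense lesion (prostate intensity minus `lesion_contrast`)
strictly inside the inner gland, mirroring the way carcinoma appears
hypointense against normal peripheral-zone tissue.  A low-order polynomial
bias field and additive Gaussian noise (sd 0.03 by default) are added and the
result is clamped to [0, 1].

Rationale: the downstream machinery — the gate, Dice scoring, and CNN
separability — only requires a contourable bright/dark structure with
realistic nuisance factors (noise, smooth shading), not radiological
texture.  Defaults: 128 px side (500 px works identically because all
thresholds are area fractions), prostate radius drawn uniformly from
12–22% of the image side, drawn area-preserving for random aspect ratios so
the contour area is exactly pi r^2 up to discretization.  Intensity levels
are not calibrated to any real cohort; no such calibration is published for
the source imagery.

Volumes stack slices whose gland radius follows a smooth elliptic profile
peaking at the middle slice; end slices can be empty.  Degenerate variants
(`no_prostate`, `fragmented` with three sub-threshold blobs, `blurred` with
heavy smoothing and contrast collapse) provide the failure modes the gate
must reject.

All generators consume an explicit seed and are bit-reproducible; component
seeds are derived from one global seed so the phantom, GAN, segmenter and
rater streams are independently reproducible.

## Preprocessing conventions

Decisions the source protocol leaves open, fixed here:

* **Normalization scope**: min–max over the whole volume (not per slice), so
  inter-slice contrast is preserved.
* **Crop anchor**: centered, side equal to the smaller dimension — the
  prostate is central in axial pelvic imaging.
* **Interpolation**: bilinear for images, nearest-neighbour for masks, so
  masks stay strictly binary.
* **Indices**: 1-based (the R convention) everywhere; the three middle
  contoured slices are taken from the middle of the *contoured* extent, with
  the lower median for even counts, since contours drive segmentation
  training.

## The multi-scale single-image GAN

`build_scale_schedule()` constructs the pyramid: if the image exceeds the
250 px cap its finest trained scale is scaled down to the cap, and sizes
decrease geometrically (ratio 0.75) until the smaller dimension reaches
25 px; the count is `ceil(log(25 / finest_min) / log(0.75)) + 1`, which gives
exactly 10 scales for 500 × 500 input.  The effective ratio is adjusted so
the coarsest scale lands exactly on 25 px.

Per scale a generator (conv–instance-norm–leaky-rectifier tower with a tanh
residual head, zero padding) maps noise plus the upsampled previous-scale
output to a residual; the critic is the same tower without normalization and
with a linear head averaged over pixels.  Training per scale minimizes

* critic: `D(fake) − D(real) + 0.1 · (||∇x D(x̂)|| − 1)²` at a random
  interpolate x̂ (Wasserstein critic with gradient penalty; the penalty
  gradient is computed by exact double backprop, valid almost everywhere for
  piecewise-linear critics, which is why the critic carries no
  normalization layers);
* generator: `−D(fake) + 10 · MSE(reconstruction, real)` along a fixed-noise
  reconstruction path (the coarsest scale keeps one frozen noise map; later
  scales use zero noise).

The noise amplitude at scale n is `0.1 · RMSE(upsampled reconstruction from
scale n−1, real at scale n)`, and 1 at the coarsest scale, so scales that
already reconstruct well receive little fresh noise.  Images are mapped to
[−1, 1] internally and clamped back to [0, 1] at sampling time only (no
clamping during training, which would kill gradients).

Scale indexing is 1-based from the coarsest, so scales 8, 9 and 10 of a
10-scale stack are the three finest; `generate_pool()` samples across the
three finest scales of whatever stack it trained.

Two presets: `full` (2000 iterations/scale, 32 base channels doubling every
4 scales, 3 critic + 3 generator steps — the conventional defaults at
500 × 500 scale) and `desk` (pyramid ratio 0.6 giving a 3-scale pyramid at
64 px, 8 channels, 200 iterations/scale, 1 + 1 steps), which trains in
roughly two minutes on one CPU.  The desk preset is what the test suite
exercises end to end; the full preset shares every code path and differs
only in configuration.

All networks here (and below) are implemented from first principles on
im2col convolution primitives with hand-written backpropagation; every
gradient path, including the penalty double backprop, is verified against
central finite differences in development and the optimizer behaviour is
covered by the training tests.

## The segmenter and the quality gate

The segmenter is a depth-2 encoder–decoder with skip connections (8 base
channels, 3 × 3 kernels, leaky rectifiers, single-channel sigmoid output
thresholded at 0.5).  Protocol constants: learning rate 1e-5, batch size 3,
3000 steps, checkpoints at 15 epochs (675 steps for 135 pairs at batch 3),
1000 and 3000 steps.

One deliberate deviation: the update rule is plain stochastic gradient
descent on *pixel-summed* binary cross-entropy (averaged over the batch),
not an adaptive-moment optimizer.  Adaptive-moment steps are invariant to
the loss scale, so 3000 steps at 1e-5 would bound total parameter motion by
about 0.03 — provably unable to train a randomly initialized network.  With
plain gradient descent the stated rate is meaningful because the pixel-sum
supplies the scale, and the checkpoint Dice trajectory then reproduces the
protocol's qualitative trend (rapid rise, near-saturation by the final
checkpoint).

The gate operationalizes the single-unbroken-boundary rule as: exactly
one 8-connected foreground component, and area at least
4% of the image (10,000 px at 500 × 500).  Interior holes do not fail the
gate: a filled region's outer boundary is unbroken regardless of holes.
The gate runs on the raw thresholded prediction, with no largest-component
post-processing.  Percent formatting offers both truncation (10,932 /
250,000 prints as 4.3) and half-up rounding (19,481 / 250,000 prints as
7.8) because the published values use both conventions; truncation is the
default, and the 253-of-654 pass rate likewise prints as 38.6 under
truncation.

## Rater-study scoring

Table conventions: false positives are conventional images answered
synthetic; false negatives are synthetic images answered conventional.
Denominators (not stated in the source tables) are per-group rater × image
answer counts, the only convention well-defined for multi-rater groups.
Concordance is mean pairwise agreement, the natural extension of
"proportion of the same answers" beyond two raters.  Reported percentages
are rounded half-up to integers, matching the published presentation.  The
chi-square test is Pearson's without continuity correction; the Wilcoxon
signed-rank test drops zero differences, averages tied ranks and uses the
exact distribution up to n = 25 untied differences; the two-sample t test
pools variances by default.  The published p-values depend on raw rater
responses that are not available, so the tests are validated against
brute-force oracles (full 2^8 sign enumeration, direct-formula statistics)
rather than against those p-values.

## Desk-scale problem sizes and what the tests show

The test suite runs entirely on phantoms: a 64 px desk-preset GAN run (three
scales, 200 iterations each), a 135-pair segmenter run at 64 px and 3000
steps, 20 held-out clean phantoms and 20 degenerate ones, a 2000-replicate
rater simulation on the 26 + 34 design, and 1000-mask component-counting
oracles.  Classifier experiments use 48 px phantoms: the lesion spans
roughly 18–30% of the gland radius, so below ~48 px it shrinks to a pixel
or two and stops being a learnable cue after three pooling stages.  These
sizes keep the whole suite within desktop minutes while leaving every
algorithmic path identical to a full-scale run.

Passing these tests shows that the machinery is correct and internally
consistent on images whose structure the phantom controls; it does not show
that the GAN produces radiologically convincing texture, that the segmenter
transfers to patient anatomy, or that human raters would behave like the
simulated ones.  Those claims require real imagery and real readers, which
this package deliberately replaces with synthetic stand-ins.

## Known limitations

* Phantom texture is piecewise-constant plus noise; classifiers can
  separate classes from cues simpler than those in real MRI.
* The GAN's full preset is CPU-expensive; no GPU path is provided.
* The segmenter is single-organ and 2D by design.
* NRRD support covers the subset the pipeline writes (raw/ascii, single
  scalar field); 16-bit PNG export is grayscale only.
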