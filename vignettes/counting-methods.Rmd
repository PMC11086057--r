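---
title: "Counting shrimp fry by density-map regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting shrimp fry by density-map regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Estimating the number of shrimp fry in a breeding tank from a single
top-down photograph is a dense small-object counting problem: each animal
is an elongated dark body a dozen pixels long, bodies overlap and occlude
each other, and per-image counts range from a handful to a thousand.
Detection-based counting misses small and occluded animals, so `frycount`
takes the regression route: learn a per-pixel *density map* whose spatial
integral is the count, supervised only by one point annotation per animal.

## From points to density maps

An image with $N$ annotated positions $x_i$ defines an impulse field
$H(x) = \sum_{i=1}^{N} \delta(x - x_i)$.  Convolving it with an isotropic
Gaussian kernel $G_\sigma$ gives the regression target
$F(x) = \sum_i \delta(x - x_i) * G_\sigma(x)$.  The package uses
$\sigma = 3$ pixels by default, evaluates each kernel at pixel centres
around the continuous (sub-pixel) annotation, truncates the support at
$4\sigma$ for speed, and — by default — renormalises every kernel so that
its on-grid, in-bounds mass is exactly 1.  Renormalisation makes the
headline invariant exact: `integrate_density(gaussian_density(ps))`
equals the point count to within float rounding even for border-adjacent
points, where an untruncated kernel would lose clipped mass.  The strict
unrenormalised convention remains available via `renormalize = FALSE`.
Coordinates are 0-based `(x = column, y = row)`; coincident annotations
accumulate (two animals can genuinely share a pixel).

## The network

`build_countnet()` realises a fully convolutional density regressor:

* **Frontend** — 13 VGG-style 3x3 convolutions with ReLU.  Only the first
  three 2x2 max poolings are kept, so the output `F2` sits at 1/8 of the
  input resolution with 512 channels (later poolings of the
  classification layout are dropped; this reconciles "13 convolution
  layers" with a 1/8-resolution head).  Inputs are standardised per
  channel with the usual VGG preprocessing constants before the first
  convolution: with raw `[0, 1]` tank images the large DC background
  component otherwise dominates every feature and the local contrast
  signal (dark bodies on a light bottom) is a small ripple on top of it.
* **Multi-scale fusion** — the 1/4-scale frontend tap `F1` is resampled
  down, a 1/16-scale map `F3` (3x3 convolution + pooling of `F2`) is
  resampled up, `[F1, F2, F3]` are concatenated along channels and
  projected back to 512 channels by a 1x1 convolution.  Bilinear
  (half-pixel, align-corners-false) resampling is used in both
  directions for symmetry.
* **CBAM attention** — channel attention (a shared bottleneck MLP over
  the global average- and max-pooled channel vectors, reduction 16,
  sigmoid-gated) followed by spatial attention (a 7x7 convolution of the
  stacked channelwise mean/max maps, sigmoid-gated).  The attention
  hyperparameters are the standard ones from the CBAM literature.
* **Decoder** — five 3x3 convolutions with dilation 2 (widths
  512/512/256/128/64 before the width multiplier) and a final 1x1
  projection to one channel.  The 1/8-scale raw map is bilinearly
  upsampled to the full input resolution *inside* the differentiable
  graph, so the network is trained through the upsampling and no manual
  count rescaling factor is needed.

Both the fusion block and the attention block can be switched off
independently (`fusion_enabled`, `cbam_enabled`), which spans the four
ablation configurations from "plain frontend + decoder" to the full
model.  A `width_multiplier` scales every channel count; `1/8` gives a
CPU-trainable miniature used throughout the tests.

### Output head: linear, not rectified

The output projection is linear by default (`output_activation = "none"`,
with `"relu"` available).  This is a deliberate deviation from a
rectified head and follows the convention of dilated-backend counting
networks.  The reason is measurable: density targets are almost empty
(zero at the overwhelming majority of pixels), so from a random
initialisation a ReLU head starts with only a sliver of active output
pixels; those pixels mostly sit on empty background and receive purely
downward gradient, and since dead ReLU pixels receive no gradient at all,
the head collapses to the all-zero map within a few SGD steps at every
learning rate we tried.  A linear head keeps every pixel trainable.

### Initialisation

Two schemes coexist:

* `build_countnet()` initialises for from-scratch training: He Gaussian
  weights in the frontend, *near-identity* weights in the backend
  (centre-tap pass-through, group-averaged when a layer narrows, plus
  small Gaussian noise), and a small-Gaussian (std 0.01) output
  projection so the initial map is approximately flat.  The identity
  backend matters: the untrained frontend's features already carry the
  count signal (a linear readout of `F2` predicts counts with r = 0.98
  on the synthetic benchmark), but random narrowing projections in the
  decoder destroy that information before it reaches the head
  (r = 0.07), and a few hundred SGD steps cannot rebuild seven scrambled
  layers.  Identity initialisation preserves the signal path from the
  start — the same motivation as identity-oriented schemes in the
  literature (Net2Net, Fixup).
* `init_weights()` applies the published recipe — backend weights
  `Normal(0, 0.01^2)`, biases exactly 0 — which presumes a *pretrained*
  frontend.  Pretrained classification weights are not bundled (they are
  tens of megabytes of third-party binary data), so requesting
  `use_pretrained_frontend = TRUE` raises an instructive error, and the
  frontend fallback is He init; the literal small-Gaussian frontend is
  available via `frontend = "gaussian"` but attenuates a 13-layer signal
  to numerical zero and is only useful for studying that failure.

## Training objective

The loss is $L = L_E + \alpha\,L_{SSIM}$ with $\alpha = 0.001$.
$L_E$ is the Euclidean loss $\frac{1}{2B}\sum_b \lVert \hat F_b - F_b
\rVert^2$ (sum over pixels, halved, averaged over the batch — the
convention under which very small learning rates such as $10^{-7}$ are
meaningful; a per-pixel mean variant is available).  $L_{SSIM} = 1 -
\frac{1}{B}\sum_b \mathrm{SSIM}(\hat F_b, F_b)$ uses the standard
windowed protocol: an 11x11 Gaussian window of scale 1.5 px, local
means/variances/covariance over the valid region, stabilising constants
$c_1 = (0.01 L)^2, c_2 = (0.03 L)^2$ with dynamic range $L = 1$ applied
to the density maps as-is (the source work calls them "constants"
without giving values).  The windowed-mean reading of the SSIM sum is
adopted; a global-statistics variant sits behind `windowed = FALSE`.
Gradients of both terms are computed analytically and are verified
against finite differences in the test suite.

## Optimisation recipe

`train_config()` defaults to the published recipe: SGD, momentum 0.95,
weight decay 5e-4, batch size 10, 300 epochs, learning rate 1e-7,
768 x 576 centre crops, and two independent 50% augmentations
(horizontal mirror, 180-degree rotation — the source description is
ambiguous between one transform and two, so both are implemented and
individually toggleable).  Training returns the weights of the epoch
with the lowest validation MAE together with the full per-epoch history
(train-until-converged descriptions of this procedure name no concrete
stopping rule, so the package trains the full budget and checkpoints the
best epoch).  Everything is driven by one seed: shuffling, augmentation
draws, and initialisation reproduce bit-for-bit in single-threaded mode.

The default rate 1e-7 is faithful to the source recipe but is tied to
full-size images, thousand-object counts, and a pretrained frontend.
The scaled-down experiments in this package (192 x 144 scenes, counts
5-40, width multiplier 1/8, from-scratch weights) use 6e-5, chosen from
a learning-rate sweep over {1e-6, 1e-5, 3e-5, 6e-5, 1e-4}: at 1e-6
validation MAE does not move within 30 epochs, at 1e-4 the fitted
count-response slope overshoots, and 6e-5 converges to a near-unit
slope within the 30-epoch budget.

## Evaluation

`evaluate_countnet()` integrates the predicted map of every image
(`predict_count()`), compares with the annotation count, and reports
$\mathrm{MAE} = \frac{1}{N}\sum |y_i - \hat y_i|$ and $\mathrm{RMSE} =
\sqrt{\frac{1}{N}\sum (y_i - \hat y_i)^2}$, overall and per density
level (Low [0, 249], Medium [250, 499], High [500, 749], Higher
[750, 1000]).  Images whose dimensions are not divisible by 8 are
reflect-padded for inference and the map is cropped back.

## The synthetic scene generator

Because the original tank photographs are not publicly available, the
package ships a generator that emulates the acquisition setting: a light
tank bottom (background level 0.75) under diffuse light with a mild
radial vignette, and 0-1000 fry per frame rendered as anti-aliased
quadratic-Bezier strokes, 8-22 px long, 1.5-3.5 px wide, slightly
curved, with dark body intensities (0.05-0.35) and additive Gaussian
pixel noise (std 0.02).  The annotation is the stroke centroid (the
labelling convention of the original data is unknown; the centroid is
the symmetric choice).  The default dataset plan reproduces the
documented split bookkeeping exactly: 390 training, 63 validation and
103 test images spread over the four density levels (121/139/105/25,
21/15/14/13, 55/11/19/18), each image's count drawn uniformly within its
level's range.  All randomness flows from explicit per-call seeds, and
a given seed reproduces images and annotations bitwise.

`easy_benchmark()` is the deliberately easy end of the generator: small
192 x 144 scenes, 5-40 well-separated high-contrast fry, low noise.  It
exists so that a width-1/8 model can demonstrably learn to count on a
single CPU in minutes.  What such runs show is that the implementation
— labels, forward/backward passes, loss, optimiser — is correct and
that the architecture can extract count-relevant features from images;
they say nothing about accuracy on real tank photographs, crowded
scenes, water optics, or biological appearance variation, none of which
the generator models.

## Numerical choices and degenerate inputs

* Truncation at $4\sigma$ with per-kernel renormalisation (see above);
  `truncate = Inf` evaluates full-grid kernels.
* Impulse matrices round half-up (ties toward +infinity).
* Max pooling uses ceil-mode so odd intermediate grids cannot break the
  1/16-scale branch; bilinear resampling always targets `F2`'s exact
  grid.
* The SSIM window must fit inside the map; a larger window is an error.
* Empty datasets, zero-epoch fits, batch sizes exceeding the dataset,
  non-divisible-by-8 training crops, out-of-bounds annotations (unless
  explicitly clamped) and negative counts all raise immediate errors.
* Checkpoints round-trip weights bit-exactly.

## Scales used by the shipped experiments

The test suite and the acceptance script run entirely on synthetic data
at desk scale: conservation and oracle checks on grids up to 256 x 256,
SSIM checks on 32 x 32 maps, shape/ablation sweeps at width 1/32 up to
768 x 576 inputs, the count-recovery experiment at width 1/8 on
60 + 12 + 20 easy scenes for 30 epochs, and the full 556-image dataset
plan rendered at 192 x 144.  These sizes are the package's own choice of
a reproducible desk-scale experiment; the full-size recipe remains the
configuration default.

## Known limitations

* No pretrained frontend is bundled, so nothing here reproduces the
  original work's absolute MAE/RMSE on real imagery; the package
  verifies the method's machinery, not those numbers.
* The generator's fry are texture-free strokes; domain transfer to
  photographs is out of scope.
* Training is single-threaded and CPU-bound by design (deterministic
  mode); full-size, full-width training at 300 epochs is impractical
  without hardware acceleration.
* Only SGD is implemented, matching the published recipe; there are no
  learning-rate schedules or mixed precision.
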