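---
title: "Cumulative inhibition and coarse-to-fine filter learning: methods"
author: "mrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative inhibition and coarse-to-fine filter learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnet)
```

## The model

`mrnet` implements an unsupervised hierarchical network that models how
visual acuity and multi-resolution representation can develop from input
statistics alone. Each layer owns a *filter bank*: a 2-D array of kernels
`W` (a `j x i` matrix; `j` kernels of length `i`) applied to every
receptive-field patch of its input. All maps are linear:

* bottom-up activation: `A = I W^T`, where `I` is the `n x i` matrix of
  gathered patches (`im2row`);
* top-down synthesis: `TD = I_TD W`, scattered back by overlap-summing
  `row2im`.

There are no nonlinearities, biases, pooling stages or weight sharing
tricks beyond the convolution-like patch gather; the model's content is
entirely in the learning rule.

### Cumulative inhibition

The bank carries a binary inhibition topology `M` (`j x j`): entry
`(a, b) = 1` means kernel `a` inhibits kernel `b`. In the default
(`"printed"`) topology a kernel is inhibited by every kernel whose bank
*row* is less than or equal to its own, so inhibitive pressure accumulates
row by row; `"strict_raster"` instead accumulates kernel by kernel in
row-major order. Both are reflexive. For each patch `p` and target kernel
`t` the *inhibition buffer* is the reconstruction of the patch by `t`'s
inhibitors,

```
B(p, t) = sum_s M[s, t] * A[p, s] * W[s, ]
```

and the weight update moves every kernel toward the residual its
inhibitors leave unexplained, gated by its own activation:

```
dW[t, ] = alpha * sum_p A[p, t] * (I[p, ] - B(p, t)),      W <- W + dW.
```

Kernels low in the bank face little inhibition and settle on the dominant
(coarse, low-frequency) structure of the input; kernels in later rows see
that structure already subtracted and are forced onto residual, finer
detail. This is the mechanism that produces a coarse-to-fine gradient
along the bank rows, the model's account of developing acuity.

`weightDelta()` evaluates the update in the algebraically collapsed form
`alpha * (A^T I - (A^T A * M^T) W)` (element-wise `*`), which is exactly
the tiled tensor formulation but never materialises the `n x (j*i)`
buffer; `inhibitionBuffer()` builds the buffer explicitly for inspection,
and the test suite asserts element-wise agreement of both against naive
triple-loop oracles (relative tolerance 1e-9, absolute 1e-12).

With the strict raster topology and a single-column bank the masked Gram
matrix becomes lower-triangular and the update is precisely Sanger's
generalised Hebbian (deflation) rule, so the kernels converge to the
leading eigenvectors of the input covariance. The suite verifies both the
structural identity and the spectral convergence. The printed topology is
the row-wise relaxation of that rule: kernels within a row deflate
against whole rows, not individuals, which is what lets a row share one
inhibition level.

The printed form of the topology predicate makes its second clause
(within-row column order) redundant, so column order inside a row never
matters; we implement the printed semantics as the default and expose the
strict raster order as an explicit variant rather than silently
"correcting" the rule.

## Architecture and geometry

The default configuration is the four-layer reference setup:

| layer | receptive field (cells) | bank `j_r x j_c` | dilation gap | grid | patch length `i` | packed output | nominal coverage |
|---|---|---|---|---|---|---|---|
| 1 | 3 x 3 (pixels) | 3 x 12  | – | 34 x 34 | 9    | 102 x 408 | 3 px |
| 2 | 3 x 3 | 10 x 20 | 2 | 28 x 28 | 324  | 280 x 560 | 9 px |
| 3 | 2 x 2 | 12 x 24 | 5 | 22 x 22 | 800  | 264 x 528 | 18 px |
| 4 | 2 x 2 | 8 x 16  | 11 | 10 x 10 | 1152 | 80 x 160  | 36 px |

with learning rate 5e-4 everywhere and a 36 x 36 input in `[0, 1]`.
Layer 1 slides contiguous stride-1 windows over the image. A layer's
output interleaves its cell grid with its bank layout (`packOutput()`),
so higher layers gather *cell blocks* — whole `j_r x j_c` sub-tensors —
and must dilate: consecutive gathered cells of a window are separated by
`gap` cells (6 x 24 output elements for layer 2's gap of 2). Windows
slide with stride 1 in lower-cell units; the gaps 2, 5, 11 are the values
that reproduce the grid sides 28, 22, 10. The stated per-layer coverage
(3, 9, 18, 36 pixels) composes multiplicatively and is *nominal*: for
layers 3 and 4 the dilated windows actually span fewer input pixels
(15 and 27) than the nominal doubling suggests, an inconsistency inherent
to combining the printed grid sides with a single gap rule; we report
both and correct neither.

Top-down regeneration starts from any layer's activation and repeatedly
applies `topDownPatches()` and the overlap-summing scatter until an image
emerges (`reconstruct()`). The whole cascade is linear, which is what
makes filter imaging trivial: a unit one-hot activation of kernel `k`
regenerates exactly that kernel's receptive field (`visualizeFilter()`).

### Overlap handling

`row2im` returns raw overlap sums plus the overlap-count grid. For a
single layer the interior counts are constant and harmless, but in
multi-layer cascades the dilated scatter's counts (1 to 9 per cell) form
a periodic multiplicative envelope on the intermediate activations — the
square artifact visible in regenerated images. Left uncorrected, this
envelope dominates reconstruction error: in the two-layer study below it
caps the centred cosine similarity far below what the very same weights
achieve when each stage's scatter is divided by its own counts (overlap
averaging, `reconstruct(..., normalize = TRUE)`), which approaches the
single-layer ceiling. `reconstruct()` therefore keeps the
raw sum as its default (the algebraic identities and the filter-imaging
convention are defined on it), while the training metrics, snapshots and
the command-line reconstruction use the count-normalising mode.

## Training protocol

Training is layer-wise (`trainLayerwise()`): layer 1 adapts first; once
its stopping rule fires it is frozen and the next layer trains — the
model's analogue of a critical period, with lower areas stabilising
before higher ones. Two bottom-up streams feed every iteration: a
*variable* stream (a fresh image each iteration) and one *constant*
target image; each stream's weight delta is applied sequentially. The
constant image's reconstruction is the quantity monitored throughout.

Two monitors are maintained:

* **Stopping metric** — `d_t`, the mean absolute pixel difference between
  the constant image and its min-max normalised reconstruction through
  the layers trained so far (top-down from the current layer's own
  activation). The rule smooths `|d_t - d_(t-1)|` with an exponential
  moving average (coefficient 0.99, i.e. a few-hundred-iteration memory)
  and stops when it falls below 1e-4, after a 50-iteration burn-in; the
  first iteration has no derivative and never stops. A layer that
  exhausts its iteration cap is reported as such, never silently.
* **Similarity trace** — every 5th iteration, the cosine similarity
  between the constant image and the *full-model* reconstruction (top
  layer fed back down, untrained upper layers included), after cropping
  2 pixels of frame artifact and min-max normalisation. The trace uses
  the mean-centred variant of `cosineSimilarity()` because overlap
  summation and min-max normalisation leave an arbitrary intensity
  offset; the plain min-max cosine of two nonnegative images is pushed
  toward 1 by their shared DC component and hides most of the learning.

### Learning-rate scaling

The reference rate 5e-4 is the package default. For scaled
configurations, a layer whose rate is `NA` receives
`alpha = 0.5 / E`, where `E` is the total patch energy of one iteration
across both streams (`autoLearningRate()`). `E` bounds the largest
eigenvalue of the per-iteration Gram matrix, so `alpha * lambda_max <=
0.5` keeps the linear learning dynamics contractive with a factor-2
margin. The margin matters: at higher layers the patch covariance is
nearly rank-one (`lambda_max` close to `E`) and with two streams an
unmargined rate oscillates and diverges. At the reference scale the rule
lands within a small factor of 5e-4 for layer 1.

Weights initialise uniformly in `[-0.01, 0.01]` from a seeded generator —
a small symmetric start that keeps early activations and buffers small —
and no renormalisation, decay or clipping is applied by default (an
optional magnitude clip exists as a divergence guard). Grayscale inputs
are mapped to `[0, 1]`.

## Synthetic streams

`streamPair()` emulates the training regime without any external data: a
variable stream plus one constant target, every image a pure function of
`(kind, size, seed, iteration)` via a fixed per-iteration seed derivation
(`streamSeed()`), so runs replay bit-identically.

* `pinkNoiseImage()` synthesises `1/f^beta` textures in the frequency
  domain (amplitude `f^(-beta/2)`, seeded phases, DC removed, min-max to
  `[0, 1]`); `beta = 2` gives the near log-linear radial power profile of
  natural images, which is the input property the model's coarse-to-fine
  account rests on.
* `gratingImage()` and `blobScene()` provide oriented sinusoids (with a
  Nyquist guard) and seeded Gaussian-blob scenes for spectral and
  fixture tests.
* `loadCifarStream()` can read local CIFAR-10 binary batches (luminance
  conversion 0.299/0.587/0.114, symmetric zero-padding from 32 x 32 to
  the input size by default, bilinear resizing as an option); it is never
  required by any test and a missing file is a hard error.

What the synthetic streams do *not* emulate: the phase structure of real
scenes (edges, contours, objects), photographic faces, and label
semantics. Passing the qualitative training checks on pink noise shows
that the mechanism orders filters by spatial frequency under natural
second-order statistics; it says nothing about object-level structure.

## The scaled two-layer study

The qualitative training properties are exercised on a study sized for a
single CPU: a 24 x 24 pink-noise pair; layer 1 with 3 x 3 fields and a
3 x 8 bank at `alpha = 5e-4` for 800 iterations; layer 2 with 3 x 3
cell windows, gap 2, a 6 x 2 bank and the automatic rate for 6000
iterations. The 6 x 2 top bank (12 kernels over 216-dim patches) keeps
the reference architecture's defining top-layer property — a strict rank
bottleneck (128/1152 there) — which is what makes the untrained
reconstruction genuinely poor and the subsequent rise meaningful; with
overlap averaging, a more generous bank starts too close to its own
ceiling. The study asserts:

* the smoothed similarity trace is non-decreasing over its final half and
  its plateau exceeds the baseline at iteration 2 of the top layer's
  phase by at least 0.2 (the baseline convention of the regeneration
  experiment: snapshot iterations are counted as the top layer
  stabilises, the lower layers being already frozen);
* the Spearman correlation between bank-row index and the spectral
  centroid of the regenerated filter rows is positive — the assertable
  core of the coarse-to-fine claim.

Reproducing the near-perfect plateau of the full four-layer system on a
natural-image stream is deliberately out of scope: it depends on a
photographic target image and an external image stream that the package
does not bundle.

## Spectral analysis

`imageSpectrum()` radially averages the 2-D discrete power spectrum into
integer-frequency annuli (cycles per image; for regenerated filter
images, cycles per receptive field — a dimensionless, size-comparable
unit chosen because hertz are undefined for static images).
`rowPowerSpectrum()` averages the linear power of each bank row's
regenerated filters and reports dB relative to the profile maximum — a
relative-power convention, since only the shape of the profiles carries
information about the coarse-to-fine ordering; all-zero
weights yield a defined all-zero profile with a warning.
`spectralCentroid()` weights annuli by their bin counts, making it the
power-weighted mean over the full 2-D spectrum — without the count
weighting, per-annulus means dilute high-frequency peaks by annulus
circumference. Whether the reference row spectra were 1-D or radially
averaged 2-D is not stated; radial averaging is used because it is
rotation-agnostic and comparable across layers of different sizes.
Parseval consistency of the binned spectrum is asserted in the suite.

## Numerical choices and degenerate inputs

* Grid coordinates are 0-based in the documentation, row-major
  throughout; windows are half-open; kernel `k` maps row-major to bank
  position `((k-1) %/% j_c, (k-1) %% j_c)`.
* Oracle comparisons use relative tolerance 1e-9 (absolute 1e-12).
* Min-max normalisation of a constant image is defined as all zeros; a
  zero-norm image inside `cosineSimilarity()` returns 0 with a warning.
* The stopping metric's first iteration has no derivative and is defined
  as no-stop; the EMA initialises at the first observed `|delta|`.
* `smoothTrace()` clamps windows that would span fewer than two points,
  with a warning; smoothing a constant trace returns the constant.
* Non-finite weights after an update abort with a diagnostic naming the
  largest delta magnitude rather than propagating NaNs.

## Limitations

* The transformation is holistic: no figure-ground separation, no
  perceptual grouping, no category-specific shaping; representations are
  building blocks, not percepts.
* Top-down signals are used for generation only; attentional modulation
  of the upward stream is not modelled.
* The nominal pixel-coverage account of layers 3-4 conflicts with the
  strict window spans (above); both are reported.
* Stability of the linear rule depends on the input scale through
  `alpha`; the automatic rate bounds the per-iteration step but is an
  energy argument, not a convergence proof.
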