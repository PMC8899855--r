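---
title: "End-to-end optimization of simulated phosphene vision: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-to-end optimization of simulated phosphene vision: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cortical visual prostheses stimulate primary visual cortex through an
electrode array; each stimulated electrode evokes a phosphene — a localized
flash of light at a retinotopically determined position.  The percept an
implant can convey is extremely coarse, so the preprocessing step that turns
a camera image into a stimulation pattern largely determines how useful the
device is.  Rather than hand-designing that preprocessing (edge filters,
segmentation front-ends, and so on), `phosphenr` treats the whole chain as
one trainable system:

1. an **encoder** (a fully convolutional network) maps a grayscale image to
   a binary stimulation protocol — one on/off decision per electrode;
2. a fixed, differentiable **phosphene simulator** renders the percept the
   protocol would evoke;
3. a **decoder** (a residual image-to-image network) reconstructs the
   task-relevant content from the simulated percept.

All three stages are optimized jointly: the loss on the decoder output is
backpropagated through the simulator and the binary quantizer into the
encoder.  The decoder plays the role of a stand-in for the downstream
visual system: whatever it can recover from the percept is what the percept
actually carries.

## Model components

### Encoder

The encoder is a fully convolutional network (3×3 kernels throughout):
a conv stage, two conv+max-pool stages, a stack of residual blocks, and two
final conv stages.  Every layer except the output uses batch normalization
and leaky rectification (negative slope 0.01, a conventional default).  Two
stride-2 pooling stages make the output grid one quarter of the input side:
a 128×128 image yields the 32×32 protocol of a 1024-electrode array.

Because current cortical interfaces cannot modulate phosphene brightness
reliably, electrode activation is **binary**.  The output layer applies a
Heaviside step (threshold 0, with the measure-zero boundary `x = 0` mapped
to 1).  During backpropagation the step's zero-almost-everywhere derivative
is replaced by the **straight-through estimator**: the upstream gradient
passes through unchanged (a clipped variant that zeroes the gradient where
`|x| > 1` is available as an option).  `heaviside_ste()` exposes the
quantizer; the tests verify that the surrogate is the exact identity.

For arbitrary phosphene maps the convolutional head cannot be used (there
is no grid to align with), so the encoder is built in "vector" mode: the
penultimate feature map is flattened and a fully connected layer emits one
logit per phosphene, followed by the same quantizer.  We deliberately keep
the *flattened* feature map rather than pooling it globally — a fully
connected head already loses the convolutional weight sharing, and pooling
would remove all spatial information, leaving the spatial regularizer
(below) with nothing to work with.

### Phosphene simulator

The simulator has **no trainable parameters**; it is a frozen, linear map
from protocols to percepts, which makes its Jacobian constant and the whole
pipeline differentiable.

*Regular grid.*  Phosphene `(i, j)` is nominally centred at
`spacing/2 + i·spacing` pixels (8-pixel spacing on a 256-pixel canvas for
the 32×32 grid).  Each centre is distorted by a uniform jitter of up to
0.25 of the spacing per axis and frozen; each phosphene gets a fixed random
brightness gain in [0.5, 1.5], mimicking natural variation.  Rendering
deposits `gain × activation` at the (nearest-pixel) centre and convolves
the canvas with a Gaussian kernel of σ = 1.5 px, truncated at 3σ and
normalized to unit sum (the truncation loses < 0.3 % of the mass; borders
are zero-padded).

*Custom map.*  To model cortical magnification — phosphenes grow and thin
out with eccentricity — a map is a set of `n` precomputed 256×256 basis
images, one peak-1 Gaussian blob each, and the percept is simply the
weighted sum `SPV = Σ wᵢ Pᵢ`.  Blobs are sampled with polar angle
`φ ~ U(π, 3π/2)` (lower-left visual-field quadrant; fixation at the canvas
corner) and eccentricity drawn through the skewed density `x + 2x²` with
`x ~ U(0, 1)`.  The printed form of that law spans [0, 3] while the centres
must fit the unit quadrant, so we normalize by its maximum:
`r = (x + 2x²)/3 ∈ [0, 1]`; this preserves the density skew while honouring
the stated bounding square.  Sizes follow `σ = 2r + 1` in pixels (σ ∈ [1, 3]
px, comparable to the regular map's 1.5 px).  Blobs are peak-normalized, not
mass-normalized, so eccentric phosphenes are larger but not dimmer; the
basis is stored as a sparse matrix (support truncated at 3σ).  Whether the
original formulation intended a normalizing denominator or mass-normalized
blobs is not decidable from the text; both choices are recorded here and
the map serializer stores per-phosphene centres and sizes so either variant
can be reproduced.

### Decoder

The decoder mirrors standard residual image-to-image designs: three conv
stages (the third with stride 2), four residual blocks, and two final conv
stages, with a logistic output (values in (0, 1)) and no normalization on
the output layer.  A 256×256 percept maps to a 128×128 reconstruction.
Residual blocks use the post-activation layout — two (conv → batch-norm)
stages with leaky rectification between, the skip connection added before
the block's final activation.

## Losses

With reconstruction `x̂`, reference `x`, protocol `s` (M electrodes):

* **Pixel loss** `L_I`: mean squared intensity error, averaged over batch
  *and* pixels, so it lives on the same scale as the reported MSE metric.
* **Sparsity loss** `L_S`: batch-mean L1 norm of the protocol, divided by M
  so a fully active binary protocol scores 1.  The normalization makes the
  trade-off weight scale-free; a raw-sum mode is available.
* **Total loss**: `(1 − κ) L_I + κ L_S` with κ ∈ [0, 1].  Sweeping κ trades
  reconstruction fidelity against stimulation sparsity — relevant because
  chronic electrical stimulation is itself a cost to neural tissue.
* **Perceptual loss** `L_P`: mean over batch and feature maps of squared
  differences between deep features of `x` and `x̂` at depth `d` (default
  3), where `d` counts rectified convolution stages from the input.  The
  extractor is pluggable; the package ships a VGG-style stack with seeded
  random weights, since random deep features are an established stand-in
  for pretrained perceptual features and keep the package self-contained.
  Grayscale inputs are replicated to the extractor's channel count.
* **Boundary loss** `L_B`: class-weighted binary cross-entropy against a
  binary boundary map, with positive-class weight `w = 0.925` chosen by the
  inverse-ratio rule (boundary pixels are rare); `boundary_class_weight()`
  recomputes `w` from data.
* **Spatial regularization** (custom maps only): unweighted cross-entropy
  between each phosphene's binary activation and the target intensity
  sampled at that phosphene's centre, scaled into the target's resolution.
  It restores the spatial coherence that the fully connected head does not
  inherit from convolutional weight sharing.  Mixing weight defaults to 1
  (the original account does not state one).  Because the activations sit
  exactly on {0, 1}, this term clamps probabilities at 0.01 rather than at
  the generic 1e−7 used inside the other logs: the straight-through
  gradient then stays finite and bounded at the saturation points instead
  of vanishing (gradient of the clamped constant) or exploding (1/ε).

Every log is clamped (ε = 1e−7); every loss has an analytic gradient that
the tests check against finite differences.

## Training procedure

The system is trained as a single unit with Adam (learning rate 1e−3,
batch 16 at full scale).  Because a particular weight initialization can
strand the encoder–quantizer combination in a poor basin, training uses
**random restarts**: the model is trained `k = 5` times from different
initializations (restart `r` seeds the weights with `master_seed + r`) and
the run with the lowest validation loss is kept.  Early stopping monitors
validation loss with patience 10 within a 100-epoch budget; both are
conventional defaults, surfaced in `train_config()`.  All randomness
(weights, shuffling, maps, data) derives from the master seed, so a run is
bit-reproducible on a fixed BLAS.

Batch-normalization evaluation uses the running statistics accumulated
during training (momentum 0.1); the selected checkpoint carries its own
buffers, which resolves the otherwise-open question of whether evaluation
statistics are frozen — they are.

## Synthetic data

The package generates everything it trains on, so no downloads are needed.

*Character images.*  Binary 128×128 images with one lowercase letter at a
uniformly random position, drawn in one of 47 "fonts" — deterministic
parameter sets (stroke width, slant, aspect, size) applied to a procedural
stroke-based glyph renderer (segments and elliptic arcs stamped with a
round pen, nominal glyph height 48 px).  Font styles 1–38 are reserved for
training and 39–47 for validation, so validation probes unseen letter
shapes.  A procedural renderer was chosen over host-font rasterization
because the original 47 fonts are unnamed and graphics-device rendering is
not reproducible across systems; the cost is that the glyphs are simpler
than real typefaces, so the dataset under-represents fine serif/stroke
detail.  Defaults: 1000 training and 234 validation images.

*Labeled scenes.*  As a stand-in for a natural-image segmentation dataset,
scenes are textured ellipses and rectangles (half-axes uniform on
[0.08, 0.22] of the canvas side, 1–4 objects, later objects occluding
earlier ones) on a low-frequency textured background, each with an integer
label map.  These scenes have exact labels and object-scale statistics but
none of the texture clutter, lighting, or class diversity of natural
images, so boundary-task results on them demonstrate that the pipeline
learns — not how it would score on natural scenes.

*Boundary maps.*  A pixel is a boundary pixel iff any 4-neighbour carries a
different label; both sides of an edge are marked.  On generated scenes the
boundary fraction is a few percent, which is the regime the 0.925 class
weight matches.

## Evaluation

`image_metrics()` reports MSE, SSIM (11×11 Gaussian window, σ 1.5, data
range 1), PSNR (`−10·log₁₀ MSE`, `Inf` for identical images), and FSIM.
FSIM is implemented from its published formulation — phase congruency from
a log-Gabor filter bank (4 scales × 4 orientations) combined with Scharr
gradient magnitude (constants T1 = 0.85, T2 = 160 on a 0–255 scale).  FSIM
has no single canonical reference implementation, so the package relies on
its identity and symmetry properties in tests and treats absolute FSIM
values as implementation-specific.  Boundary predictions are scored with a
full ROC sweep (all distinct thresholds, trapezoid AUC, tie-aware) plus
accuracy/sensitivity/specificity/precision at an operating threshold
(default 0.5); the AUC agrees with the all-pairs rank statistic and with an
independent reference implementation in the tests.  Task comparisons use
paired t-tests on minibatch metrics at α = 0.05 with Bonferroni correction;
zero-variance difference vectors are flagged as degenerate rather than
silently producing a t statistic.

The conventional-preprocessing baseline converts an image to Canny edges
(σ = 1 smoothing, hysteresis thresholds 0.1/0.2 on [0, 1] intensities —
common defaults, as the original choice is unstated), activates an
electrode iff its image block contains an edge pixel, and trains **only the
decoder** on the resulting percepts.  A holistically nested edge detection
baseline is intentionally out of scope (it requires pretrained weights);
the baseline registry leaves a slot for it.

## Problem sizes used by the tests and the acceptance script

The package's default preset reproduces the full-scale geometry (128×128
images, 32×32 grid, 256×256 percepts, widths 8/16/32 and 16/32/64, five
restarts).  Training that on a single CPU is a multi-hour undertaking, so
the shipped test suite and `scripts/acceptance.R` run a **desk-scale
preset**, chosen once as the package's own reduced geometry
(`desk_scale_overrides()`):

* 32×32 images through an 8×8 grid (64 electrodes) onto a 64×64 canvas at
  the standard 8-px spacing and σ = 1.5 px;
* glyph height 20 px — a proportional scaling (12 px) would leave a glyph
  spanning ~3 electrode pitches versus ~12 at full scale, making the task
  qualitatively harder than the original; 20 px keeps roughly five pitches
  per glyph;
* widths 4/8/16 with two residual blocks on both networks; learning rate
  2e−3 (fewer total updates at this scale), batch 16;
* 200 training / 50 validation images, 15 epochs, 2 restarts for the
  reconstruction experiment; κ ∈ {0, 0.3, 0.6} with one restart per κ for
  the sparsity sweep; 200 synthetic scenes, 12 epochs for the boundary
  experiment.

At this scale the reconstruction model beats the mean-training-image
baseline by a wide margin, the sweep reproduces the negative
activation-versus-κ slope (and the positive MSE slope), and the boundary
decoder scores well above the 0.5 chance AUC — the same qualitative
findings as the full-scale experiments, at a few minutes each.  These
checks are computed by the test suite and the acceptance script; nothing in
this vignette reports a number the code does not recompute.

## Numerical choices and degenerate inputs

* Step threshold at 0 with `x = 0 → 1`; jittered centres rounded to the
  nearest pixel before deposition; centre collisions accumulate brightness.
* Gaussian kernels truncated at 3σ and renormalized; simulator borders
  zero-padded.
* Protocol/map shape mismatches, out-of-range κ, invalid widths, non-binary
  protocols passed to the sparsity metric, and single-class ROC targets all
  raise immediately (the last with a flagged `NA` AUC rather than an
  arbitrary value).
* Training aborts a restart with a warning if the loss goes non-finite;
  `random_restarts()` errors only if every restart diverged.

## Limitations

The simulator is deliberately static: no temporal stimulation dynamics
(pulse trains, inter-stimulus intervals), no electrode interactions or
current spread, and no retinal-implant axonal streak distortions.  The
perceptual loss uses random (not pretrained) features unless an extractor
is supplied.  Subjective percept quality is outside what these simulations
can establish; reconstruction metrics are proxies for information content,
not for usability by an implant wearer.
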