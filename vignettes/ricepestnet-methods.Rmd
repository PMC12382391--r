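---
title: "RicePestNet: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RicePestNet: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RicePestNet)
```

# The problem

Detecting rice pests in field imagery is hard for two reasons that compound
each other: the scenes are visually adverse (pests camouflaged against
foliage, partial occlusion by leaves, motion blur from hand-held capture,
strong illumination shifts), and deployment targets are computationally
constrained, which rules out large detectors. RicePestNet implements a
lightweight single-stage detection toolkit built around a nano-scale
anchor-free architecture with two efficiency/accuracy modifications — ghost
convolutions in the backbone and a context-aggregation attention block in the
neck — together with shape-aware box regression and slide-weighted
classification losses. Every stage is exercised on synthetic scenes so the
whole pipeline is testable without field data.

# Architecture

The baseline is the nano variant of the familiar single-stage family: depth
multiple 0.33, width multiple 0.25, backbone widths 16–32–64–128–256 with
C2f blocks, an SPPF pyramid at the backbone top, a path-aggregation neck with
two top-down and two bottom-up fusion stages, and three decoupled heads at
strides 8/16/32. Box regression is distribution-focal: each box side is a
16-bin categorical distribution whose softmax expectation gives the offset;
the 16-element expectation projection is a fixed (non-trainable) buffer,
which is why every variant's gradient count is exactly 16 below its
parameter count.

## Parameter accounting

All convolutions are bias-free and followed by batch-norm affine pairs, so a
standard block holds `cin*cout*k^2 + 2*cout` parameters. The classification
branch hidden width follows the reference head rule
`max(ch_P3, min(nc, 100))`, where `ch_P3 = 64` is the first detect-level
width; this is the configuration under which the closed form reproduces the
published counts at both `nc = 15` and `nc = 80`.

```{r params}
totalParams(countParams(buildModel(modelConfig(nClasses = 15))))
totalParams(countParams(buildModel(modelConfig(nClasses = 15,
                                               ghost = TRUE, ca = TRUE))))
```

## Ghost convolution

A ghost block replaces each of the four stride-2 backbone convolutions
(0-based layer ids 1, 3, 5, 7). The primary branch keeps the replaced layer's
3×3 kernel and stride 2 but emits only half the output channels (the
intrinsic features); the cheap branch derives the other half by a true
depthwise 5×5 convolution (one filter per channel) of the intrinsic features.
Both halves get batch norm and SiLU. This is the unique simple configuration
whose per-layer savings (1,904 / 8,416 / 35,264 / 144,256 = 189,840 in total)
reproduce the published parameter reduction; descriptions of the block
elsewhere (1×1 primary kernel, `groups = 7`) are internally inconsistent with
that arithmetic and were not followed. `compressionRatio()` and
`speedupRatio()` evaluate the ideal-ratio algebra, which tends to the ghost
ratio `s` as channels grow.

## Context aggregation

The context-aggregation block is a simplified non-local attention placed on
the 384-channel tensor formed when the deepest neck stream is upsampled and
concatenated with the stride-16 backbone stream — the point where the
large-object and medium-object streams fuse — immediately before the
following C2f. A scalar key projection is softmaxed over the `N = H*W`
positions and aggregates a value projection into a single global context
vector, which is added back at every position, modulated by the softmax of a
second scalar projection (the reweighting map). The projections are 1×1
convolutions **with** bias followed by batch norm (the two scalar projections
carry 387 parameters each, the value projection 148,608), totalling 149,382
at 384 channels — again the unique simple 1×1 layout matching the published
parameter delta; whether the original authors used one insertion or two
cannot be reconciled with that delta under any standard two-insertion layout,
so a single insertion is used. Zeroing the value projection recovers the
identity map, which the tests assert.

# Losses

## Shape-aware IoU

Box regression minimises

`L = 1 - IoU + distance_shape + 0.5 * Omega_shape`

where the center-distance term is normalised by the squared diagonal of the
smallest enclosing box (`c2 = (cw^2 + ch^2 + eps)^alpha`, `eps = 1e-7`,
`alpha = 1`) and both the distance and the shape-discrepancy term
`Omega = sum_t (1 - exp(-omega_t))^theta` (`theta = 4`) are weighted by
coefficients `ww, hh` derived from the ground-truth aspect ratio through a
`scale` exponent. `scale` defaults to 0 (no printed value exists for it),
which collapses `ww = hh = 1`; it is exposed as a parameter. The analytic
gradient is implemented alongside the loss and verified against central
differences at 1e-4 relative tolerance; at the piecewise switches
(coincident box edges, equal sizes) the implementation takes one-sided
subgradients.

## Slide-weighted classification

Classification is binary cross-entropy, reweighted per positive sample by the
slide function: weight 1 for IoU at least 0.1 below the threshold `mu`,
`exp(1 - mu)` in the transition band, and `exp(1 - x)` above it, so samples
near the threshold — the hard examples — are up-weighted while easy samples
keep weight 1. The printed piecewise conditions of the source formula are
self-contradictory; the canonical three-branch form above is used. `mu` in
`"auto"` mode is the mean IoU of the batch's positive samples, recomputed
each step (the threshold is described as adaptively learned, with no schedule
given); a fixed value can be supplied instead. Weights apply to the
classification terms of assigned positives; background anchors keep
weight 1.

## Assignment and distribution-focal loss

Positive samples come from a task-aligned assigner: each ground truth takes
its top-10 anchors by `score^0.5 * IoU^6` among anchors whose point lies
inside the box; anchors claimed twice keep the ground truth of highest
overlap; target scores are the alignment metric normalised per ground truth
to peak at its best overlap. The distribution-focal term is cross-entropy on
the two integer bins bracketing each continuous side offset, linearly
weighted. Loss gains are 7.5 (box), 0.5 (classification), 1.5
(distribution-focal).

# Augmentation algebra

Affine transforms use the row-vector convention `[x' y' 1] = [x y 1] %*% M`:
translations occupy the last row and the last column is `(0,0,1)'`. Rotation,
y-shear, shift and anisotropic scale are the four primitives; angles are
accepted in degrees and converted internally. `applyAffine()` conjugates the
transform with shifts of the canvas centers, so a 90° rotation of a square
canvas stays in view; images are resampled through the inverse map with
bilinear interpolation, and each box is mapped corner-wise to its
axis-aligned hull, clipped, and dropped if its visible area falls below 10%
of the transformed area or a side drops under 2 px (unstated in the source;
set to common detector practice).

HSV conversion follows the hexcone model: value is the channel maximum, hue
is piecewise by dominant channel with a +360 wrap, and saturation — bounded
but never defined in the source formulas — uses the standard hexcone
`(V - min)/V`. Letterbox has two policies: `stretch` (independent axis
ratios, exact target, no padding — the stated default path) and `pad`
(single `min` ratio with symmetric gray padding). The source's prose
"the larger ratio is selected" would overflow the target and contradicts its
own usage; the conventional `min` is used in `pad` mode and the
contradiction is simply not propagated. Mosaic letterboxes four
independently augmented images onto a 2×2 board (default twice the train
size) and remaps labels into board coordinates.

`augmentObjectSet()` is the sixfold-expansion driver: each annotation yields
exactly `multiplicity` augmented instances. Because random affine draws can
lose boxes to clipping, a draw that would change the count is retried and
ultimately falls back to photometric-only jitter, making per-class output
counts exactly `multiplicity ×` the input counts — the invariant the
expansion table of the emulated survey requires.

# Synthetic scenes

`generateScene()` emulates the nuisance structure of field imagery: a
low-frequency green-brown value-noise background, elliptical "pests" with a
per-class characteristic hue (±8° jitter), axis ratio 1.2–3 and area 0.2–8%
of the canvas (log-uniform; configurable through `areaRange`), foliage
stripes drawn over objects after rendering, motion blur by a random line
kernel, and a multiplicative illumination factor. Class frequencies default
to the annotated-object counts of the 15-class survey the package emulates
(`ricePestClasses`), giving the same strong imbalance (797 vs 3 instances).
Masks record the full object extent even when an occluder covers part of it,
matching a whole-pest annotation convention — the occlusion question
(visible vs full extent) is unresolved in the source and full extent was
chosen because the detector is meant to localise occluded pests.

Seeding is counter-based: scene `i` of root seed `s` uses a stream derived
from `(s, i)`, so datasets are reproducible regardless of generation order.
Rendered images are quantised to 8 bits so in-memory scenes equal their PNG
round trip.

What the generator does **not** emulate: real pest morphology and texture,
leaf geometry, depth-of-field, compression artifacts, or correlated
backgrounds. Passing tests on these scenes demonstrate that the pipeline's
geometry, losses and bookkeeping are correct — not that the detector would
reach any particular accuracy on field imagery.

# Evaluation

Matching is greedy per class in descending confidence with one match per
ground truth at the IoU threshold. AP integrates the interpolated
precision envelope; the discretization is not stated in the source, so the
dominant 101-point convention is the default with a `continuous` (all-point)
alternative. Zero-denominator precision/recall are defined as 0, and classes
with neither ground truths nor detections are excluded from the class mean.
mAP@0.5:0.95 averages the per-threshold mAP over 0.5 to 0.95 in steps of
0.05.

# Training at desk scale

The driver trains with SGD (momentum 0.937, weight decay 5e-4), cosine decay
from `lr0 = 0.01` to 1% of itself, and linear warmup over the first 3 epochs
with the bias group starting at 0.1. The printed warmup momentum of 1.5 would
be non-contractive, so the effective momentum is clamped at the nominal value
during warmup. Mosaic is active except in the final `closeMosaic` (default
10) epochs. The best checkpoint is selected by validation mAP@0.5.

Two choices specific to CPU-scale runs:

* **Batch-norm recalibration.** With only tens of optimisation steps, the
  exponential running-statistics update (momentum 0.03) is far from the
  activation distribution, and eval-mode predictions are meaningless while
  train-mode learning is fine. `calibrateBatchNorm()` therefore replaces the
  running moments by exact cumulative means over a set of forward passes; the
  trainer runs it before each validation pass. On long runs this converges to
  the same statistics the exponential update would reach.
* **Problem sizes.** The test suite trains at 64 px (the smallest size
  divisible by all three strides that leaves a 8×8 top-level grid), batch 1
  (maximising optimisation steps for a fixed epoch budget), on 50
  single-class scenes with high-contrast blobs at 15–30% canvas area — a
  deliberately separable distribution. Five epochs suffice for the loss to
  descend and validation mAP@0.5 to exceed 0.5 under these conditions; this
  validates the training loop end to end, nothing more.

# Numerical choices

* Pixel boxes are half-open `[x0, x1) × [y0, y1)`, 0-based; labels are
  normalized center-size; `cornerToCenter()`/`centerToCorner()` are the only
  conversion paths.
* Batch norm uses eps 1e-3 and biased batch variance; SiLU throughout
  (a stray mention of LeakyReLU in the source's component description is
  treated as a citation artifact).
* Convolution backward uses the injectivity of each kernel tap's
  output-to-input map, so the col2im scatter is a plain indexed add.
* The classification head's final bias is initialised to -4.595
  (sigmoid ≈ 0.01) and the box head's final bias to 1, standard
  stabilisation for early training.
* DFL targets are clamped to `[0, regMax - 1 - 0.01]`; the assigner treats
  its outputs (assignments, target scores, slide weights) as constants in the
  backward pass, as in reference implementations.
* Ties: the greedy matcher takes the first maximal-IoU ground truth;
  `which.max` order resolves assigner ties (measure-zero under continuous
  scores).

# Known limitations

* Pure-R training is desk-scale only; a 640 px forward pass takes seconds
  and full-scale training is out of reach (by design — the published
  full-dataset accuracies are GPU-scale and are not reproduced here).
* Alternative IoU losses from the source's comparison table (MPDIoU, GIoU,
  WIoU) are not re-derived; the ablation hook is `boxLoss = "iou"` plus
  `clsLoss = "bce"`, which recovers the standard baseline objective.
* No exponential moving average of weights, no mixed precision, no
  distributed training; none are part of the method.
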