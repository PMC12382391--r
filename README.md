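# RicePestNet

A lightweight single-stage detection toolkit for rice pest imagery, written
in R. It is aimed at researchers in agricultural image analysis who want a
fully inspectable, dependency-light implementation of a modern anchor-free
detector — architecture, losses, augmentation, evaluation and training — that
can be exercised end to end on synthetic field scenes, without a GPU and
without external datasets.

## What it implements

**Architecture.** A nano-scale single-stage detector (depth multiple 0.33,
width multiple 0.25): a 16–32–64–128–256 backbone of C2f blocks with an SPPF
pyramid, a path-aggregation neck, and three decoupled heads at strides
8/16/32 with distribution-focal box regression (16 bins per side, frozen
expectation decode). Two modifications target field imagery on constrained
hardware:

* **Ghost convolutions** replace the four stride-2 backbone convolutions:
  half the output channels come from a standard 3×3 convolution, the other
  half from a cheap depthwise 5×5 transform of those intrinsic features,
  saving 189,840 parameters in total.
* A **context-aggregation block** on the 384-channel top-down neck fusion: a
  spatial softmax over a scalar key projection aggregates a value projection
  into one global context vector per image, re-injected residually under a
  learned per-position reweighting map (+149,382 parameters).

Parameter accounting is exact and closed-form: the baseline at 15 classes
holds 3,013,773 parameters, the combined ghost + context-aggregation model
2,973,315 (2,973,299 trainable — the 16-element decode projection is fixed).

**Losses.** Shape-aware IoU box regression

```
L = 1 − IoU + distance_shape + 0.5 · Ω_shape
```

with enclosing-box-normalised center distance and a shape-discrepancy term
`Ω = Σ_t (1 − e^{−ω_t})^4`, both weighted by ground-truth aspect
coefficients through a `scale` exponent; an analytic gradient is provided
and verified against central differences. Classification is slide-weighted
binary cross-entropy: weight 1 for easy samples, `e^{1−μ}` in a band below
the IoU threshold `μ`, `e^{1−x}` above it, with `μ` adapting to the batch's
mean positive IoU. Positives come from a task-aligned assigner
(`score^0.5 · IoU^6`, top-10 per ground truth). Gains: 7.5 / 0.5 / 1.5 for
box / classification / distribution-focal.

**Augmentation.** The classical algebra in the row-vector matrix convention
(`[x' y' 1] = [x y 1]·M`): rotation, shear, shift, scale with exact box
remapping through corner hulls; hexcone HSV conversion and multiplicative
jitter; letterbox (stretch and pad policies); 2×2 mosaic; and a
multiplicity driver that emits exactly k augmented instances per annotation.

**Evaluation.** Greedy confidence-ordered matching, precision/recall/F1,
AP via the interpolated precision envelope (101-point default), mAP@0.5 and
mAP@0.5:0.95.

**Synthetic scenes.** `generateScene()` renders textured foliage backgrounds
with elliptical "pests" (per-class hue, multi-scale sizes), foliage
occluders, motion blur and illumination shifts, with instance masks,
class imbalance matching a 15-class field survey, and deterministic
counter-based seeding; `writeDataset()` writes YOLO-format labels, PNGs and
a dataset YAML.

## Worked example

```r
library(RicePestNet)

# exact architecture accounting
pr <- countParams(buildModel(modelConfig(nClasses = 15, ghost = TRUE, ca = TRUE)))
pr
#> ParamReport: 2,973,315 total, 2,973,299 trainable, 24 layers

# a reproducible synthetic dataset
cfg <- sceneConfig(imageSize = 64, objectsPerImage = c(1, 3), seed = 0)
scenes <- lapply(0:19, function(i) generateScene(cfg, i))
scenes[[1]]
#> MaskedScene: 64x64 px, 3 instance(s) of 3 class(es)
man <- writeDataset(scenes, "pest-demo", seed = 0)
# -> 16 train / 4 val images; labels like
#    "5 0.757812 0.203125 0.046875 0.093750"  (class cx cy w h, normalized)

# the bespoke losses
shapeIoULoss(c(0.5, 0.5, 0.2, 0.2), c(0.6, 0.5, 0.2, 0.4))
#> [1] 0.8519843
slideWeight(c(0.30, 0.45, 0.80), mu = 0.5)
#> [1] 1.000000 1.648721 1.221403
f1Score(0.89959, 0.82258)
#> [1] 0.8593632
```

The parameter report says the combined model is 40,458 parameters lighter
than the 3,013,773-parameter baseline while adding the attention block; the
shape-IoU value is the full three-term loss for a prediction offset from a
taller ground-truth box; the slide weights show the characteristic bump just
below the threshold (1.649 = e^0.5) decaying above it; and the F1 value is
the harmonic mean of the quoted precision/recall pair.

Training and prediction run the same way at any scale
(`trainModel()`, `predictModel()`, `evaluateModel()`); the test suite trains
a 5-epoch model on 50 separable synthetic scenes at 64 px in under a minute
on one CPU. A thin command-line wrapper with `synth`, `params`, `train`,
`eval` and `predict` subcommands is installed at
`inst/cli/ricepestnet.R`.

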