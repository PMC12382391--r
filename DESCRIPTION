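Package: RicePestNet
Title: Lightweight Single-Stage Detection Toolkit for Rice Pest Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable toolkit for building, training and evaluating a
    lightweight anchor-free single-stage detector for rice pest imagery.
    Provides a synthetic field-scene generator with ground-truth masks and
    YOLO-format dataset export, the classical detection augmentation algebra
    (affine transforms with exact box remapping, HSV jitter, letterbox,
    mosaic), a declarative YOLOv8n-family architecture builder with
    ghost-module convolutions and a context-aggregation attention block and
    exact closed-form parameter accounting, shape-aware IoU and slide-weighted
    classification losses with analytic gradients, detection evaluation
    (precision/recall/F1, AP, mAP), and a CPU training/prediction driver.
    The network layers (convolution, batch normalisation, SiLU, pooling,
    nearest upsampling) are implemented on BLAS-backed matrix operations with
    hand-derived backward passes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
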