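Package: uwdet
Title: Attention-Augmented CSP Detector for Underwater Organism Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, profiles, trains and evaluates a single-stage anchor-based
    detector for marine organisms in degraded underwater imagery. The backbone is
    a cross-stage-partial design with large 5x5 kernels and channel attention
    (CSPNeXt/CSPLayer); the neck carries a bottleneck-transformer block (BoT3)
    with content-only multi-head self-attention on the medium detection head.
    Includes a two-step underwater image enhancement (local adaptive color
    correction plus locally adaptive contrast improvement) used for union dataset
    augmentation of training splits, YOLO-layout dataset input/output with
    letterbox and mosaic augmentation, a synthetic underwater scene generator for
    fully self-contained experiments, and a complete evaluation stack
    (precision, recall, per-class AP, mAP over IoU thresholds, PR curves and
    confusion matrices) with analytic parameter and FLOP accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
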