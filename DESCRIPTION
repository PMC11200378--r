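Package: mcpose
Title: Top-Down Multi-Chicken Pose Estimation and Keypoint Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for evaluating multi-animal (chicken) pose estimation.
    Implements the chicken keypoint similarity (CKS), a Gaussian-kernel
    keypoint similarity over a 10-point chicken schema, greedy instance
    matching, COCO-style 101-point average precision and recall averaged
    over ten similarity thresholds (mAP/mAR), PCK, per-keypoint pixel error
    and RMSE, a top-down detect-then-pose pipeline scaffold with pluggable
    detector and pose backends, heatmap decoding, and a seeded synthetic
    multi-chicken scene generator with a configurable prediction noise
    model, so the full evaluation stack is testable without any external
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
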