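Package: dosevision
Title: Machine-Vision Quality Control for 3D-Printed Dosage Forms Trained
    on Synthetic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and stress-testing machine-vision quality
    control pipelines for 3D-printed (stereolithography) dosage forms when no
    photographic training data exist. Provides a deterministic procedural
    rasterizer that renders top-down images of capsules, tablets and
    orodispersible films in good and defective states (cracked, over-cured,
    under-cured), a domain-shifted photograph-like test-set generator, and
    out-of-distribution distractor images. Includes image standardization
    (square resize, luma grayscale, flattening), 16-fold test-set augmentation
    (center crops crossed with flips and 180-degree rotation), seven classical
    learners with cross-validated grid search behind a single fitting
    interface, evaluation metrics (accuracy, sensitivity, specificity,
    rank-based AUROC, Brier score, most-confident profiles), and a stress
    harness covering scalability, probability calibration and
    out-of-distribution robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    png,
    jsonlite,
    yaml,
    rpart,
    ranger,
    xgboost,
    e1071,
    nnet,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
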