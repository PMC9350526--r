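Package: microseg
Title: Coarse-to-Fine Cascade Segmentation of Micro-Lesions in 2D Susceptibility-Weighted Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage cascade network for automated segmentation of small
    hypointense lesions (cerebral-microbleed-like micro-objects) in 2D
    susceptibility-weighted MRI slices. Stage one is a residual U-Net that
    coarsely detects candidate lesions on the whole slice; fixed-size regions
    of interest centred on the candidates are then segmented at full
    resolution by a second network built around a residual atrous spatial
    pyramid pooling block. Training uses a joint binary cross-entropy, Dice
    and sensitivity loss designed for extreme foreground/background
    imbalance. The package includes the complete forward/backward
    convolutional engine, an Adam trainer with early stopping and k-fold
    cross-validation, a pixel- and lesion-level evaluation suite
    (sensitivity, precision, Dice, F2, Jaccard, Matthews correlation,
    per-image false positives, precision-recall curves), NIfTI/PNG image and
    mask input/output, and a seedable synthetic phantom generator so the
    whole pipeline is trainable and testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    png,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
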