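Package: overlapseg
Title: Multilabel Segmentation of Overlapping Cell-Culture Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-pixel multilabel segmentation of phase-contrast microscopy
    images of cancer cell cultures grown on vascular structures. Because the
    six structure classes (vascular networks, noninvasive cells, invasive
    cells, invasive spikes, spheroids, perispheroid cell matter) are
    semitransparent and mutually non-exclusive, one specialized binary
    encoder-decoder network is trained per class. The package implements the
    full pipeline: balanced positive/negative tile sampling, label-consistent
    augmentation, a U-Net style encoder-decoder with hand-rolled
    backpropagation and Adam (RcppArmadillo), a pixel-wise batch-weighted
    softmax cross-entropy loss with L2 regularization, staircase learning-rate
    decay, overlapping-grid stitched full-frame inference, and per-class
    evaluation (sensitivity, specificity, Dice, ROC/AUC with DeLong
    confidence intervals, error overlays). A seeded synthetic phantom
    generator emulates the overlapping-class image structure so the whole
    pipeline is testable end-to-end without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
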