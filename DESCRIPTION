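Package: speckleseg
Title: Unsupervised Domain Adaptation for Cerebral Vessel Segmentation
    in Laser Speckle Contrast Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments cerebral vessels in laser speckle contrast images
    (LSCI) without target-domain labels. Labeled fundus-style vessel
    photographs are size-matched to the thicker cerebral vessels
    (morphological dilation or vessel-density patch selection), translated
    into synthetic speckle images by a cycle-consistent adversarial
    synthesis network, and used to train a patch-based U-Net segmenter
    under a Dice loss, in either a two-stage or an end-to-end regime.
    Includes an Otsu-threshold baseline, confusion-matrix evaluation
    metrics with mean and standard-error aggregation, majority-vote ground
    truth construction, a seeded synthetic vessel-image generator for both
    domains, and a compact CPU training engine (Rcpp convolutions with
    hand-derived backpropagation and Adam) powering the networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
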