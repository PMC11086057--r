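Package: frycount
Title: Density-Map Regression for Counting Shrimp Fry in Tank Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for counting small dense aquatic animals (shrimp fry)
    in top-down tank images by density-map regression.  Point annotations are
    converted to ground-truth density maps with a fixed-bandwidth Gaussian
    kernel; a fully convolutional network with a VGG-style frontend,
    multi-scale feature fusion, convolutional block attention (CBAM) and a
    dilated decoder regresses a full-resolution density map whose spatial
    integral is the predicted count.  Training uses stochastic gradient
    descent on a Euclidean loss optionally combined with a structural
    similarity (SSIM) term, and evaluation reports per-image MAE and RMSE
    with density-level breakdowns.  A seeded synthetic scene generator
    renders fry-like elongated dark strokes with exact point ground truth so
    the whole pipeline is testable at desk scale without proprietary data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
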