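Package: tomoQC
Title: Quality Assessment and Dose Analysis for Cellular Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-slice quality scoring of cellular cryo-electron tomograms
    with a residual convolutional regressor, aggregation into a per-tomogram
    quality metric (TomoScore) and a slice-count thickness estimate, plus the
    supporting machinery: MRC2014 volume and movie-stack input/output, a
    synthetic tomogram and tilt-movie generator with category-graded slice
    quality, even/odd frame-split dose fractionation, Fourier ring
    correlation, robust (RANSAC) thickness regression, and log2 dose-response
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
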