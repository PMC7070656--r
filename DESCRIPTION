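Package: shoalcount
Title: Fish Shoal Counting from Underwater Images by Density-Map Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the number of fish in a shoal from single
    underwater images. Implements grey-world piecewise-linear color correction
    and Sobolev-norm contrast enhancement for underwater imagery,
    geometry-adaptive Gaussian density-map supervision built from point
    annotations, a hybrid counting network combining a multi-column
    convolutional front end with a dilated convolutional back end, a
    batch-size-one Adam training loop, the standard counting evaluation suite
    (MAE, RMSE, MAPE, accuracy, Pearson correlation, range-stratified
    accuracy, error histograms), and a seeded synthetic fish-shoal scene
    generator with Gaussian and salt-and-pepper noise augmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
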