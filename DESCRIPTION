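Package: uavyield
Title: Plot-Level Soybean Yield Parameter Estimation from UAV RGB Imagery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for estimating soybean yield parameters
    (grain number per plant and grain weight per plant) under lodging from
    multi-date UAV RGB orthomosaics and digital surface models. Extracts
    plot-level RGB vegetation indices, excess-green canopy cover, crop
    height from DSM-DEM differencing with Otsu bare-ground estimation, and
    gray-level co-occurrence matrix texture statistics; screens features
    with a shadow-feature (Boruta-style) random-forest procedure and
    one-class SVM outlier rejection; and fits five regression families
    (PLSR, penalized linear, random forest, SVR, feed-forward network)
    over nested feature sets and acquisition-date sweeps. Includes a
    synthetic field generator emulating a 1,805-plot trial so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    ranger,
    e1071,
    glmnet,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
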