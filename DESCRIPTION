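Package: cellstack3d
Title: 3D Cell Localization from Single Acquisitions of Lensless Fluorescence Imagers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Recovers three-dimensional cellular information from single
    acquisitions of millimeter-scale lensless fluorescence imagers. Provides a
    Perlin-noise phantom generator for tumor-cell images, a depth-dependent
    point-spread-function forward model with single- and opposing dual-sensor
    geometries, seeded convolutional networks for depth classification, image
    deblurring and multi-layer per-pixel cell detection, the associated
    pixel-level evaluation metrics (error rate, sensitivity, specificity, ROC),
    and voxel-level 3D reconstruction export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    tiff,
    png,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
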