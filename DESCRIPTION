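Package: popfluor
Title: Single-Cell Bioreporter Fluorescence Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies promoter-activity heterogeneity in bacterial
    populations from paired phase-contrast and fluorescence micrographs.
    Provides a synthetic micrograph and population generator with known
    ground truth, phase-contrast segmentation with morphological mask
    refinement and size-filtered particle detection, shape-descriptor
    measurement (ellipse fit, Feret calipers, solidity, circularity,
    roundness), machine-learning cell/non-cell classification (L1-penalised
    logistic regression and random forest with cross-validated tuning),
    percentile-mask background estimation and per-image fluorescence
    correction, and population statistics: moment skewness and kurtosis,
    an interquartile-range baseline criterion for high-fluorescence cells,
    relative-fluorescence summaries, top-quantile subpopulation fold
    changes, and the associated hypothesis tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    rlang,
    withr,
    EBImage,
    tiff,
    glmnet,
    ranger,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
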