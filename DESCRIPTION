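Package: ovseg
Title: Breast-Region-Guided Lesion Segmentation for DCE-MRI with Optimal-Volume Cropping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying how breast-region segmentation (BRS) affects
    deep-learning breast lesion segmentation in dynamic contrast-enhanced MRI.
    Builds four dataset variants (whole volume, BRS-masked whole volume,
    lesion-slice selection, and an optimal volume obtained by a slice/height
    optimization with a safe-distance margin and multiple-of-32 rounding),
    trains a 2D nested-UNet (UNet++) with a hybrid Dice/focal/cross-entropy
    loss under patient-level 5-fold cross-validation, and reports segmentation
    metrics, volume-stratified false-positive/false-negative lesion counts,
    annotation-density overlay maps, and carbon-footprint accounting of
    training time. A synthetic DCE-MRI phantom generator provides fully
    reproducible cohorts with ground-truth breast-region and lesion masks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
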