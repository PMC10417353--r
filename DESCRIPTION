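Package: gliotrack
Title: Post-Surgical Brain Tumor Segmentation and Longitudinal Response
    Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for post-operative glioma MRI analysis at radiotherapy
    planning and follow-up: generation of synthetic post-surgical MRI
    phantoms with ground-truth gross tumor volumes (GTV), preprocessing of
    contrast-enhanced T1-weighted and T2w/FLAIR volumes into three-channel
    model inputs, a trainable 3D U-Net for GTV segmentation with Dice loss,
    augmentation, learning-rate scheduling and early stopping, overlap and
    directed Hausdorff evaluation metrics, multi-level Otsu resection-cavity
    removal with lesion volumetry, and an automated BT-RADS longitudinal
    scoring engine driven by volumetric percent-change cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
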