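Package: triseg
Title: Multiscale Three-Pathway Convolutional Network for Brain Tumor
    Segmentation and Typing in 2D MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pixel-wise segmentation and slice-level typing of brain tumors
    (meningioma, glioma, pituitary) in 2D contrast-enhanced MRI slices using
    a convolutional network that processes each 65x65 sliding window through
    three parallel pathways with large (11x11), medium (7x7) and small (3x3)
    kernels before concatenating their feature maps. Includes a seeded
    synthetic phantom generator emulating the structure of the public
    T1-CE slice datasets (skull ring, class-distinct lesion textures, binary
    masks, border polylines), elastic-deformation augmentation, balanced
    window sampling, SGD training with stratified patient-aware k-fold
    cross-validation, sliding-window inference, and evaluation via Dice,
    sensitivity, the predicted-tumor-type ratio score and a
    confidence-thresholded confusion matrix with a non-classified category.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
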