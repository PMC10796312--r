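Package: petnodcnn
Title: 3D Convolutional Neural Networks for PET Pulmonary Nodule
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for classifying solid pulmonary nodules as
    benign or malignant from 2-[18F]FDG PET volumes with 3D convolutional
    neural networks. Includes a seeded phantom PET cohort simulator,
    isotropic resampling and nodule-centred cropping, fold-specific min-max
    normalisation, class-balanced offline 3D augmentation (translations,
    centre rotations, Gaussian noise), three 3D CNN architectures trained
    with Adam and early stopping under stratified 4-fold cross-validation
    with size-weighted ensembling, nonparametric ROC analysis (trapezoidal
    AUC, DeLong confidence intervals and paired test, Venkatraman-Begg
    permutation test, Youden and sensitivity-constrained decision
    thresholds), comparison against the SUVmax biomarker, and 3D Grad-CAM
    visual explanations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
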