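Package: progseg
Title: Progressive Prior-Guided Auto-Segmentation for Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Progressive auto-segmentation of serial 3D images for
    fractionated adaptive radiotherapy. Implements a 3D U-Net whose skip
    connections carry convolutional LSTM memory across treatment fractions,
    so that each fraction's segmentation is informed by the planning image,
    its contours, and all previously contoured fractions. Includes a
    deformable multi-organ phantom simulator and a deformation-field
    fraction interpolator for pre-training without clinical data, a
    sequential per-fraction training loop (composite Dice and binary
    cross-entropy loss, RMSProp, plateau learning-rate schedule, per-patient
    memory clearing), baseline models without memory or without prior
    knowledge, an online inference runtime with rigid prior alignment, and
    segmentation metrics (Dice, Hausdorff, HD95, paired tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
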