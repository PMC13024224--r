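Package: gaitmt
Title: Semi-Supervised Video Classification of Leg-Alignment Gait
    Abnormalities with a Mean Teacher and Hierarchical Spatial Pooling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screening-oriented classification of short frontal-view walking
    videos into normal, genu varum (bow-legged) and genu valgum (knock-kneed)
    leg alignment. Fits a small 3D residual convolutional network whose
    terminal pooling is a spatial hierarchical pooling module (per-bin max and
    average statistics over a multi-scale grid pyramid), trained either fully
    supervised or semi-supervised with a Mean Teacher: an exponential-moving-
    average teacher provides consistency targets and confidence-gated
    pseudo-labels for unlabeled clips. Includes a synthetic articulated-walker
    video generator whose class labels are determined by frontal-plane knee
    alignment geometry, subject-level data splitting, weak/strong video
    augmentation, clinical evaluation metrics (macro precision/recall/F1,
    sensitivity/specificity/PPV/NPV, PR-AUC) and Grad-CAM saliency maps for
    the 3D backbone. All numerical optimisation (3D convolution, batch
    normalisation, backpropagation, Adam) is implemented in the package with
    compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    png,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
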