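Package: toothstage
Title: Semi-Automated Dental Developmental Staging from Radiograph Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automated pipeline for Demirjian staging (stages C-H) of
    mandibular premolars from 250x250 radiograph crops: percentile contrast
    stretch, 7x7 median filtering and CLAHE enhancement; globally optimal
    radial active-contour segmentation by dynamic programming over a polar
    candidate grid with a distance-bound smoothness constraint; polygon
    rasterization and Dice/Jaccard segmentation scoring with a parameter
    sweep over radius length and number of radial lines; label-preserving
    data augmentation; a compact convolutional network classifier (six
    stages, trained with Adam/SGD/RMSProp/AdaGrad) with architecture grid
    search and a dropout study; and an evaluation battery with confusion
    matrices, per-stage recall, Cohen's kappa and learning-curve summaries.
    Includes a star-convex tooth phantom generator producing images,
    ground-truth masks and stage labels so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    tiff,
    optparse
Config/testthat/edition: 3
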