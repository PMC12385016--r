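Package: radfuse
Title: Explainable CNN-Radiomics Fusion for 2D Radiograph Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multimodal, explainable classification of 2D grayscale
    radiographs (e.g. periapical dental images) as lesioned or healthy.
    Gradient-weighted class activation maps (Grad-CAM) from a convolutional
    backbone are thresholded into saliency masks that restrict handcrafted
    radiomic feature extraction (first-order, GLCM, GLRLM, GLDM, NGTDM and
    2D shape descriptors) to network-attended pixels. Masked radiomic
    vectors are fused with penultimate-layer embeddings, optionally
    averaged over deterministic test-time-augmentation views, reduced by
    ANOVA-F SelectKBest or PCA, and classified with random forests or
    gradient-boosted trees under stratified cross-validation. Predictions
    are explained at pixel level (heatmaps) and feature level (TreeSHAP
    attributions), and validated with paired t, exact Wilcoxon signed-rank,
    within-fold permutation, McNemar and Holm-Bonferroni procedures.
    Includes a seeded synthetic radiograph generator and a small trainable
    CNN backbone so the full pipeline runs without external data or weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    tiff,
    png,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
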