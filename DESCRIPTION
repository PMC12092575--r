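Package: odynr
Title: Slide-Level Dysplasia Classification and Malignant-Transformation
    Scoring from Segmentation Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of oral epithelial dysplasia (OED) whole-slide
    segmentation outputs. Classifies slides as dysplastic versus non-dysplastic
    via the dysplasia-epithelium ratio with an empirically selected threshold,
    computes a slide-level malignant-transformation risk score (ODYN-score)
    from 168 nuclear morphological and spatial features per patch using a
    multilayer perceptron trained by iterative draw-and-rank sampling with a
    symmetric cross-entropy loss, and provides the accompanying evaluation
    toolkit: AUROC/AUPRC, mask metrics, Mann-Whitney U with rank-biserial
    effect sizes, permutation Spearman tests, Benjamini-Hochberg FDR,
    Kaplan-Meier/log-rank, Harrell's C-index, multivariate Cox models and a
    top-ranked-tile nuclear feature analysis. A synthetic cohort generator
    (masks, nuclear polygons, clinical tables) with a controllable
    transformation effect makes every stage testable without access to
    clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
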