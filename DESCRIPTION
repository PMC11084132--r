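Package: breathnet
Title: Cross-Site Electronic-Nose Breathprint Classification with
    Augmentation and Fine-Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-site diagnostic modelling of electronic-nose
    (eNose) breathprints. Simulates two-site cohorts of 14-channel
    metal-oxide sensor traces with a controllable disease effect and site
    shift, converts traces to 14-channel 16x16 breathprint images, trains a
    small three-layer convolutional network for lung-cancer classification,
    and implements two augmentation operators - Fourier amplitude mixing
    (SDA) and noise-plus-backward-shift (NSA) - together with few-shot
    target-site fine-tuning. Evaluation covers ROC/AUC, thresholded
    sensitivity/specificity/accuracy with percentile bootstrap confidence
    intervals, subgroup accuracies, PCA embeddings, and the demographic
    contingency-table statistics used in cohort description tables.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
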