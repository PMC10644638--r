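Package: diabgan
Title: Diabetes Classification with a Semi-Supervised GAN and Clinical
    Tabular Preprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for classifying diabetes from clinical
    tabular data in the PIMA schema. Implements zero-as-missing detection
    with skewness-guided mean/median imputation, interquartile-range
    capping of outliers, fasting-glucose three-class relabeling, SMOTE
    oversampling with edited-nearest-neighbour cleaning (SMOTEENN), a
    semi-supervised generative adversarial classifier whose discriminator
    carries both an adversarial and a class head, stratified k-fold
    cross-validated evaluation (accuracy, precision, recall, F1, AUC), and
    logistic-regression feature analysis with Wald tests and odds ratios.
    Ships a synthetic PIMA-like data generator so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
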