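Package: eastils
Title: Digital Tumor-Infiltrating Lymphocyte Scoring on H&E Breast Cancer Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tumor-infiltrating lymphocytes (TILs) on hematoxylin and
    eosin stained breast cancer sections with a fully digital pipeline: per-slide
    H&E stain-vector recalibration and colour deconvolution, watershed nucleus
    detection on the hematoxylin optical-density channel, constrained cell
    expansion, morphometric and neighbourhood-smoothed cell features, a deep
    feedforward cell classifier (tumor / lymphocyte / stromal / other), and the
    easTILs% score (lymphocyte area over stromal area within the invasive tumor
    region). Includes a synthetic H&E tile and patient-cohort generator with
    exact ground truth, and the statistical toolkit used to relate easTILs% to
    pathologic complete response: Mann-Whitney, Pearson correlation, chi-square
    on dichotomized scores, ROC with DeLong AUC comparison, Kaplan-Meier and
    log-rank survival, Wilcoxon matched pairs, and multivariable logistic
    regression with marker-treatment interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    grDevices,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    png,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
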