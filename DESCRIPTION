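Package: icufair
Title: Interpretability and Fairness Auditing for ICU Mortality Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable workflow for auditing in-hospital mortality
    predictors trained on hourly intensive-care time series: a synthetic
    electronic-health-record cohort generator with planted ground truth,
    cohort selection and hourly-aggregation preprocessing into (N, T, F)
    arrays and tabular summaries, a small-model contract with input
    gradients, eleven feature-importance estimators (saliency, integrated
    gradients, gradient SHAP, noise tunnel, Shapley sampling, permutation,
    ablation, occlusion, squared discrete derivatives, glassbox, random),
    remove-and-retrain (ROAR) and trustworthiness curves, stratified-AUC
    group-fairness auditing with treatment-disparity summaries, and
    interaction statistics linking feature importance to fairness metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
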