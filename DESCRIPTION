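Package: isirs
Title: Iterative Sure Independent Ranking and Screening for Drug
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.com", role = c("aut", "cre"))
Description: Rank-based marginal utility screening (SIRS) and its
    iterative extension (ISIRS) for selecting drug-response-associated
    features from ultrahigh-dimensional multi-omics profiles.  Features
    are ranked by a model-free statistic built from the conditional
    distribution of the response, refined by lasso regression on response
    residuals, and used in an ordinary least squares prediction model
    with coefficient t-tests.  Includes cross-validated evaluation
    (Pearson correlation, mean squared error), tuning of the number of
    selected features over a grid, redundancy scoring of selected feature
    sets by absolute correlation and mutual information, simple-top-features
    and correlation-screening baselines, and seeded generators for the
    simulation scenarios the method targets, including a hidden-predictor
    design that is marginally uncorrelated with the response but jointly
    essential.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
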