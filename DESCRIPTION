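Package: qoladmap
Title: Mapping QoL-AD Questionnaire Responses to EQ-5D Utility Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating EQ-5D utility values from the Quality of Life in
    Alzheimer's Disease (QoL-AD) questionnaire when no EQ-5D data were collected.
    Implements instrument scoring with item-7 exclusion and range-preserving
    standardisation, EQ-5D-3L tariff evaluation and 5L-to-3L crosswalk lookup,
    nine direct and response mapping estimators (OLS, Tobit by maximum likelihood,
    censored least absolute deviations, two-part, and per-item multinomial,
    ordinal and least-squares response models), exact expected-utility computation
    over the 3125 five-level health states, cluster-robust covariance, model
    comparison by RMSE and MAE, JSON model serialization for applying fitted
    algorithms to new data, and a calibrated simulator of paired
    QoL-AD/EQ-5D datasets for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    quantreg,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    callr,
    lme4,
    optparse,
    sandwich,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
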