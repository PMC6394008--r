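Package: lifehorizon
Title: Life-Expectancy Prognostication from Electronic Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts a patient's remaining life expectancy (1-50 months)
    from five years of electronic-medical-record history. Provides a
    relational EMR cohort container with plain-text interchange readers and
    writers, a calibrated synthetic cohort generator with plantable
    prognostic signal, a clinical free-text normalization pipeline,
    death-anchored monthly feature engineering with ICPC/ICD code
    abstraction and frequency cut-offs, keyword feature selection by
    frequency ranking, Kullback-Leibler temporal divergence, and skip-gram
    word embeddings, a two-layer LSTM horizon classifier returning a
    probability distribution over 50 future months, and a quotient-based
    prognostic evaluation framework (33 percent proportional accuracy
    margin) with recency test splits and k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
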