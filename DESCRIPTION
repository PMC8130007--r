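Package: altriage
Title: Active-Learning Triage of Biomedical Abstracts with Random
    Negative Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pool-based active learning for high-recall retrieval of
    drug-safety drug-drug interaction (DDI) abstracts. Implements four
    active-learning workflow variants that combine uncertainty sampling in a
    probability band, random negative sampling from an unreviewed background
    pool, high-confidence positive mining, dual classifiers for the two
    negative-sample populations, and validation-set updating. Includes the
    accompanying text preprocessing (Porter stemming, term-document count
    matrices, standard-deviation feature selection), calibrated linear
    classifiers (hinge-loss max-margin and ridge logistic), precision at
    fixed recall evaluation, principal-component distribution diagnostics,
    and a topic-mixture synthetic corpus generator with a ground-truth
    labeling oracle for end-to-end experiments.
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
    glmnet,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
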