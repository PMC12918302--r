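Package: releap
Title: Reinforcement-Guided Active Learning for Phenotype Label Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for budget-constrained correction of noisy proxy phenotype
    labels in electronic-health-record style cohorts. Implements a
    reinforcement-learning agent (proximal policy optimization over the
    probability simplex of strategy-mixture weights) that adaptively combines
    uncertainty, diversity, and query-by-committee active-learning strategies,
    using the validation performance of downstream risk models (L2-regularised
    logistic regression and penalized Cox proportional hazards) as the reward
    signal. Includes a seeded synthetic cohort simulator with calibrated
    outcome and phenotype prevalences, fixed-strategy and random comparator
    arms, replication and aggregation utilities with 95% confidence intervals,
    subgroup evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    ggplot2
Config/testthat/edition: 3
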