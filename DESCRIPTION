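Package: srgprank
Title: Symbolic-Regression Variable Ranking with Statistical Validation for
    Small Clinical Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate predictors of a binary clinical outcome by their
    usage frequency across an archive of symbolic-regression models evolved by
    genetic programming under leave-one-out cross-validation, and validates the
    top-ranked variables with conventional multivariable statistics. Provides
    an expression-tree genetic-programming engine with Pareto-front
    (complexity versus 1 - R-squared) model selection and trimmed-mean
    ensembling, frequency-based machine-learning scores, a permutation test
    for classifier significance, a nine-learner classification benchmark, a
    seven-measure variable-importance suite, multivariable logistic and linear
    regression diagnostics (McFadden pseudo-R-squared, small-sample corrected
    AIC, concordance statistic, variance inflation factors), and a synthetic
    cohort generator emulating small-n, many-predictor biopsy study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    optparse
Config/testthat/edition: 3
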