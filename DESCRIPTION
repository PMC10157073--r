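Package: dtipattern
Title: Nested Cross-Validated SVM Classification of White-Matter Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-sample diagnostic classification of diffusion-MRI
    region-of-interest feature tables. Implements a repeated nested
    cross-validation pipeline around a linear maximum-margin classifier with
    per-fold min-max rescaling, greedy forward wrapper feature selection and
    hyperparameter search; permutation-based model significance; feature-weight
    stability maps (cross-validation ratio and sign-based consistency with
    false-discovery-rate control); confusion-matrix and prevalence-adjusted
    diagnostic metrics (balanced accuracy, number needed to diagnose,
    predictive summary index, number needed to predict); univariate group
    screening (Mann-Whitney U, 2x2 chi-square); post-hoc stepwise linear
    regression of model decision scores on covariates; and a synthetic cohort
    generator that plants a sparse multivariate group signal undetectable by
    per-feature univariate tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
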