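Package: aucmiss
Title: AUC Estimation for Diagnostic Accuracy Studies with Missing Index Test Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating single-test diagnostic accuracy studies with
    a continuous index test, inducing missing index values under MCAR, MAR and
    MNAR, and estimating the area under the ROC curve with eight competing
    methods: complete case analysis, chained-equation multiple imputation
    (predictive mean matching and Bayesian normal regression), joint-model
    imputation under a general location model, nearest-neighbour score-based
    multiple imputation with and without a bootstrap step, augmented inverse
    probability weighting, kernel-smoothed inverse probability weighting, and
    hot-deck imputation with an empirical likelihood confidence interval.
    Includes Monte Carlo performance summaries (bias, RMSE, coverage, power
    against a minimally acceptable AUC from Obuchowski's sample-size formula),
    a reproducible factorial simulation runner, and metamodels regressing
    performance measures on simulation parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    lme4,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
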