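Package: psmiss
Title: Propensity Score Weighting with Missing Confounder Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation framework for comparing strategies that handle
    missing values in propensity score model covariates when estimating
    the effect of a binary exposure on a continuous outcome by stabilized
    inverse probability weighting.  Implements the data generating models
    (main-effects and non-additive/non-linear exposure scenarios), four
    missingness mechanisms (MCAR, two MAR variants, and a group-correlation
    "sinister" MAR), treatment mean imputation, single stochastic regression
    imputation with and without parameter uncertainty, multiple imputation
    by chained equations, multiple imputation with a pooled missingness
    pattern indicator, propensity score estimation by logistic regression
    and by gradient boosted regression trees with surrogate splits, weight
    trimming, Rubin's rules, and a replicated evaluation harness reporting
    bias, SD, SE and RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, Rcpp, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
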