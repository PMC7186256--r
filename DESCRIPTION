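Package: resindex
Title: Robust Effect Size Index from M-Estimators and Sandwich Covariances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of a robust, model-agnostic effect size index built
    on M-estimation theory. Solves estimating equations, forms the empirical
    sandwich (robust) covariance, and derives the index from the robust Wald
    chi-squared statistic, so that effect sizes from different models share a
    single unitless scale even under heteroskedasticity or other variance
    misspecification. Includes closed-form special cases for two-group mean
    differences, simple linear regression, and logistic regression with
    nuisance covariates; conversion formulas linking the index to Cohen's d,
    f-squared, and partial R-squared with qualitative interpretation bands;
    asymptotic bias diagnostics for the classical indices under
    heteroskedasticity; model-free power and sample-size calculations via the
    noncentral chi-squared distribution; and a synthetic-data simulation
    engine that assesses finite-sample bias and standard error of the
    estimator over grids of sample size, effect size, and covariate
    correlation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    jsonlite,
    optparse
Config/testthat/edition: 3
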