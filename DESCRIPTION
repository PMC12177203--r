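Package: fcgam
Title: Copula Regression for Ratios of Correlated Gamma Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distributional regression for the ratio R = U/V of two
    positive, gamma-distributed biomarkers whose dependence -- positive or
    negative -- is induced by a Frank copula. Provides the exact density,
    distribution and quantile functions of the ratio, covariate-dependent
    maximum-likelihood fitting of the rate and association parameters,
    credible intervals from a normal posterior approximation, conditional
    median and quantile prediction, benchmark ratio-regression models
    (GB2, log-normal and gamma families with optional
    location-scale-shape predictors), a synthetic-data generator for
    correlated mixed-type covariate designs, and simulation harnesses for
    interval coverage, conditional-median accuracy and out-of-sample
    predictive log-likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
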