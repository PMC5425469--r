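Package: swinecondemn
Title: Weather-Driven "Dead" Condemnation Risk and Foregone Revenue in
    Slaughter Swine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for weekly slaughter-condemnation
    surveillance of swine that die in transit or in lairage ("dead"
    condemnations). Links slaughter plants to nearby weather stations by
    great-circle distance, builds weekly heat-index and minimum-temperature
    exposure categories, fits zero-inflated negative binomial generalized
    linear mixed models (log link, log-head offset, class-nested exposure
    effects, processing-volume random intercept) by direct maximization of
    the marginal likelihood with adaptive Gauss-Hermite quadrature, and
    derives condemnation rates, attributable risk, risk ratios, expected
    incidence, and counterfactual foregone-revenue attribution priced with
    monthly carcass price series. Includes a synthetic-data generator with
    known ground truth emulating all input streams so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    pracma,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    geosphere,
    glmmTMB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
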