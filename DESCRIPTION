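Package: polyenv
Title: Joint Polygenic and Environmental Prediction with Gene-Environment Interplay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multivariable gene-environment analysis of
    a continuous trait: polygenic score construction from GWAS summary
    statistics with an LD-block reference panel (lassosum-style penalized
    regression), joint penalized prediction from polygenic scores and
    environmental measures via elastic nets with repeated cross-validation
    and hold-out evaluation, bootstrapped nested-model R-squared comparison,
    post-selection (selective) inference through the truncated normal
    distribution, gene-environment correlation and mediation decomposition,
    and hierarchical group-lasso discovery of two-way interactions under
    strong hierarchy. Includes a calibrated synthetic-cohort generator so
    every stage is testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
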