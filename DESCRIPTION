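Package: psrglmm
Title: Pseudo-Response Generalized Linear Mixed Model Genome Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association and QTL mapping for traits that deviate
    from normality (binary, binomial, Poisson and ordinal, with gaussian as a
    special case) under the generalized linear mixed model with a marker-based
    polygenic kinship term. The mean model is linearized into a pseudo-response
    working variable whose variance components are estimated by restricted
    maximum likelihood on an eigendecomposed kinship, and the genome is scanned
    with four strategies: a plain generalized linear model without polygenic
    control, the exact mixed-model fit per marker, an approximate scan with
    variance components fixed at the null fit (P3D), and the fast pseudo-response
    scan that freezes the null working variable entirely. Includes Wald tests
    with Bonferroni thresholds, QTL-heritability summaries from ANOVA mean
    squares, and a simulation suite for power, calibration and bias studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
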