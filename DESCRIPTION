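Package: mtmim
Title: Multiple-Trait Multiple-Interval Mapping of QTL in Backcross Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint mapping of quantitative trait loci (QTL) for several
    correlated traits in a backcross population. Fits a multivariate-normal
    mixture model over unobserved multi-locus QTL genotypes by
    expectation-conditional maximization (ECM) or a hybrid EM/Newton-Raphson
    algorithm, estimates genome-wide significance thresholds by
    Gaussian-multiplier resampling of efficient scores, builds multiple-QTL
    models by forward selection with per-trait effect pruning and position
    optimization, tests pleiotropy against close linkage and QTL-by-environment
    interaction, and decomposes the genotypic variance-covariance matrix into
    per-QTL contributions. Includes a seeded simulator of backcross genotypes
    and multi-trait phenotypes for power and error-rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
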