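Package: kerndca
Title: Kernel-Based Differential Co-Expression Analysis of Gene Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether the co-expression structure of a gene pathway
    depends on one or more general (continuous, discrete, or categorical)
    risk factors. Individual-specific gene correlations are estimated as
    cross products of standardized residuals after removing mean and
    variance effects of the risk factor, covariates, and batch variables
    (group-wise variance estimation or a double generalized linear model).
    Dependence between the cross products and the risk factor is measured
    with a Hilbert-Schmidt independence criterion trace statistic under
    linear, projection, and Gaussian kernels, calibrated by a mean- and
    variance-preserving permutation algorithm, with kernel-level empirical
    p-values combined by Fisher's method. Includes an eigengene baseline,
    an optional large-sample Gamma approximation, simulators for
    multivariate-normal and negative-binomial pathway architectures, GMT
    pathway input, and study-level false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
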