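Package: omictrio
Title: Integrative Association Testing for Genotype-Methylation-Expression
    Trios with Partially Missing Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based joint association test for trios of genotype,
    DNA methylation and gene expression against a binary case-control
    phenotype. Individuals with missing methylation and/or expression values
    contribute through analytically marginalized conditional probabilities
    (a logistic-probit approximation combined with closed-form Gaussian
    integration) instead of imputation. Includes a likelihood ratio test with
    an asymptotic chi-square null, duo and single-omic variants, a trio
    catalog builder for cis-window screens, a synthetic case-control data
    generator, and a simulation harness for type I error, power under
    structured missingness, and cross-validated classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
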