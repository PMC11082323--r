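Package: ssgblup
Title: Multi-Breed Single-Step Genomic BLUP with a Joint Reference Population
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-breed genomic evaluation by single-step genomic
    BLUP (ssGBLUP). Provides a two-breed gene-drop simulator with
    Balding-Nichols founder divergence, genotype and phenotype quality
    control in the PLINK PED/MAP and dosage-matrix dialects, population
    structure diagnostics (linkage-disequilibrium decay, principal
    components of the genomic relationship matrix, kinship block
    summaries), pedigree and genomic relationship algebra (A, A-inverse,
    VanRaden G, blended H and its inverse), a bivariate animal model with
    a Gibbs sampler for variance components and genomic breeding values,
    Geweke convergence diagnostics, and a joint-reference-population
    cross-validation protocol reporting reliability, bias and inflation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
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
    coda,
    jsonlite,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
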