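Package: vineflow
Title: SNP-Panel Population Genetics and Approximate Bayesian Computation
    Scenario Choice for Germplasm Dissemination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for inferring dissemination routes of
    clonally propagated crop germplasm from SNP-array genotypes. Provides
    quality control for diploid biallelic SNP panels (missingness and minor
    allele frequency filters, duplicate-profile detection, variance-inflation
    LD pruning, allele-coverage core collections), descriptive population
    statistics (unbiased gene diversity, Weir-Cockerham pairwise Fst, Nei's
    standard genetic distance, neighbor-joining trees, linkage-disequilibrium
    decay curves, method-of-moments identity-by-descent relatedness), a
    structured-coalescent simulator for divergence/admixture demographic
    scenarios, and approximate Bayesian computation model choice with
    rejection sampling, weighted multinomial logistic regression, local-linear
    parameter adjustment, confusion analysis, and posterior-predictive model
    checking. A synthetic-data module generates SNP-array-like study panels
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    ape,
    nnet,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
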