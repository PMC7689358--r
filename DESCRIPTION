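Package: lcgp
Title: Genomic Prediction with Local Convolutional Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for benchmarking genomic prediction methods on
    simulated breeding populations. Implements local convolutional neural
    networks (LCNN) for SNP-to-phenotype prediction alongside multilayer
    perceptron and convolutional baselines, classical linear baselines
    (GBLUP with the VanRaden genomic relationship matrix, extended GBLUP
    with a Hadamard-square epistasis kernel, and BayesA via Gibbs
    sampling), a founder-haplotype and random-mating genotype simulator
    with local linkage disequilibrium, additive and epistatic trait
    architectures with heritability scaling and correlated multi-trait
    generation, and a repeated cross-validation harness reporting
    predictive ability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Matrix,
    optparse,
    Rcpp,
    stats,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
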