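Package: wkgs
Title: Weighted-Kernel Genomic Selection Across Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction of quantitative traits across environments
    with trait- and population-specific weighted kernels. Marker weights
    combine minor-allele-frequency information (through a Beta density that
    up-weights rare variants) with FDR-adjusted p-values from a
    genotype-by-environment association scan. The weighted kernels feed
    single-environment and generalized multi-environment Bayesian kernel
    mixed models, fitted by Gibbs sampling, that predict phenotypes of
    genetically heterogeneous populations (doubled-haploid lines replicated
    across environments, or disjoint half-sib families per site). Includes a
    CV2-style cross-validation harness with per-partition recomputation of
    allele frequencies and association weights, and a synthetic-data
    generator emulating the relevant population structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
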