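Package: rarecov
Title: Abundance-Weighted Coverage and Sequence Diversity of Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the abundance-weighted average coverage of a shotgun
    metagenome from read redundancy, using either an exact k-mer kernel with
    quality-based sequencing-error correction or an ungapped alignment kernel.
    Redundancy is rarefied over logarithmically spaced sequencing efforts via
    the Turing-Good principle, the resulting curve is fitted to a gamma-CDF
    sigmoid, and the fitted model yields the sequence-diversity index Nd, the
    coverage at the actual sequencing effort, and the projected effort needed
    to reach any target coverage. Includes the taxonomic diversity estimators
    used to benchmark Nd (maximum-likelihood and Dirichlet-pseudocount Shannon
    indices, Turing-Good coverage of OTU profiles) and a seeded synthetic
    community simulator with a closed-form Poisson coverage oracle.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
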