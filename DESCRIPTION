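Package: phyloconcord
Title: Concordance Factors, Coalescent Discordance and Outgroup-Choice
    Simulation for Palaeognath-Style Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting gene-tree/species-tree discordance in
    palaeognath-style phylogenomic data sets: exhaustive maximum-likelihood
    inference on small trees under GTR+Gamma, seeded sequence simulation
    (stationary and with branch-specific base composition), multispecies
    coalescent quartet-topology simulation and the closed-form concordance
    probability with its inversion, gene and site concordance factors for the
    three four-group quartet hypotheses, compositional diagnostics (GC content,
    relative compositional variability, RY-coding, matched-pair symmetry
    tests), locus filtering and divergence stratification, and a seeded
    synthetic-data generator that emulates the statistical structure of
    conserved nonexonic element, intron, ultraconserved element and
    protein-coding locus collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    phangorn,
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
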