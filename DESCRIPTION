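Package: yartsa
Title: Origin Authentication and Cophylogeography of Caterpillar-Fungus Host Moths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA-based origin authentication and cophylogeographic
    analysis of Thitarodes host moths of the caterpillar fungus Ophiocordyceps
    sinensis. Implements maximum-likelihood phylogenetic placement of query
    samples on a fixed multi-locus reference tree with likelihood weight
    ratios, a monophyly/sister rule for assigning geographic origin, loci
    subsampling sensitivity experiments, Mantel tests of isolation by distance
    with geographic-radius and phylogenetic time-slice sweeps, ParaFit and
    PACo host-parasite congruence tests, dispersal-extinction-cladogenesis
    (DEC and DEC+J) range-model fitting with AIC comparison, Mk-model
    stochastic character mapping of regional transitions, and a calibrated
    synthetic-data generator (birth-death trees, Brownian geography,
    host-switching parasite trees, multi-locus sequences with dropout) that
    emulates the statistical structure of degraded market-sample data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    geosphere,
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
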