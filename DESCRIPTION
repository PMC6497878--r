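Package: chromcomm
Title: Multiscale 3D Community Detection for Chromosome Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects 3D communities in chromosome contact maps (Hi-C or
    simulated) at every organisational scale with a single resolution
    parameter, using generalized modularity with a polymer-physics null
    model in which the expected contact weight between two loci decays
    with their genomic separation. Includes a lattice Monte Carlo
    simulator for fractal (crumpled) globules based on
    conformation-dependent polymerization, equilibrium-globule reference
    simulations, off-lattice randomization by constrained annealing,
    Knight-Ruiz matrix balancing, a seeded Louvain-style optimizer for
    the generalized modularity, and polymer/genomic post-processing
    (contact-decay and end-to-end scaling, radius of gyration,
    asphericity, segment decomposition, border overlap with reference
    annotations, and per-community signal summaries).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
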