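Package: latticegel
Title: Lattice Monte Carlo Models of Gelation and Phase Separation in
    Linear Multivalent Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained cubic-lattice Monte Carlo simulation of linear
    multivalent proteins (poly-SH3 / poly-PRM bead-tether polymers) with
    implicit (Flory-random-coil), explicit (self-avoiding) and hybrid
    disordered linkers. Provides the five-move Metropolis-Hastings kernel
    with microscopic-reversibility weights, an exhaustive enumeration
    oracle for tiny systems, order parameters that separate sol-gel
    percolation (largest-cluster fraction) from density transitions
    (radius-of-gyration ratio), droplet-radius and coexistence-boundary
    estimation, Flory-Stockmayer gel-point analytics with a random
    bipartite network calibration of the percolation threshold, the
    cooperativity ratio c*, and sequence-level linker metrics (FCR, NCPR,
    the Delta deviation from a Flory-random-coil distance profile, and the
    residue-to-lattice-site mapping).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
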