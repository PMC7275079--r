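Package: dynplex
Title: Dynamic Plex Percolation for Community Tracking in Time-Indexed
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and tracks overlapping communities in sequences of
    binary undirected graphs sharing a common vertex set, using the
    dynamic plex percolation method (DPPM): maximal k-plexes are
    enumerated per time slice and within enhanced two-slice graphs whose
    self and railroad edges let plexes walk across time, then percolated
    into dynamic communities via a minimum vertex-overlap rule.  Includes
    a clique percolation baseline with stochastic across-time linking,
    benchmark simulators for community expansion, contraction, splitting
    and merging, an edge-deletion noise experiment, a windowed
    cross-correlation functional-network inference front-end for
    multichannel voltage recordings, and sensitivity/specificity scoring
    of detections against planted community trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
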