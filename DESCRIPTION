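Package: hyplink
Title: Hyperbolic-Geometry Link Prediction for Multiplex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting missing links and identifying spurious links
    in multiplex networks using the hyperbolic geometry of each layer. Layers
    are embedded independently in the hyperbolic disk by likelihood
    maximization (HyperMap-style), node pairs are scored with classical
    similarity indices (preferential attachment, common neighbors, CAR, CJC),
    the raw hyperbolic distance, and two hybrid indices that blend popularity
    and similarity: distance-weighted common neighbors (WCN) and a Borda rank
    aggregation of common neighbors with hyperbolic distance (Rank-CN-HP).
    Per-layer scores are fused across layers weighted by interlayer link
    overlap. Includes a popularity-x-similarity optimization (PSO) network
    generator with a nonuniform angular mode, power-law exponent and
    temperature estimation, distance-bin link-probability curves, and
    repetition-based precision evaluation protocols for both missing- and
    spurious-link experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
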