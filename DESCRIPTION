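Package: nrbnkit
Title: Noisy Random Boolean Network Models of Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generation, augmentation, simulation and analysis of noisy
    random Boolean network (NRBN) models of gene regulatory networks.
    Supports random topologies (fixed in-degree, Erdos-Renyi, preferential
    attachment, power-law, small-world) and random Boolean function schemes
    (bias-based, canalyzing, logic expressions), augmentation of a fixed
    topological and functional core to a target size, synchronous attractor
    discovery (exhaustive or sampled), flip-perturbation attractor
    transition matrices, threshold ergodic set decomposition, emergent
    differentiation-tree extraction and level-by-level tree matching,
    knockout robustness (avalanches and sensitivity) and classical network
    statistics, with plain-text import/export and reproducible batch
    sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    ape,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
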