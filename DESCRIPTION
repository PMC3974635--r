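Package: wirecost
Title: Wiring-Cost-Aware Null Models for Spatially Embedded Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for attributing properties of spatially embedded, weighted,
    undirected networks (such as structural brain connectomes) to their wiring
    constraints. Generates degree-preserving surrogate ensembles by constrained
    edge rewiring (spatially unconstrained 'random', per-region
    wiring-length-conserving 'spatial', and wiring-length-reducing 'reduced'
    surrogates), constructs bottom-up minimally wired baseline networks, and
    computes a battery of complex-network metrics including global efficiency,
    Onnela weighted clustering, a small-world index, degree-clustering
    hierarchy, degree assortativity, k-core and s-core decomposition, a
    weighted rich-club density, Newman spectral modularity, and scaled
    inclusivity of module partitions, together with topological and spatial
    similarity measures and ensemble significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
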