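Package: cpepa
Title: Clinical Pathway Performance Analysis with a Stochastic Process Algebra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models clinical pathways as compositions of patient, resource and
    waiting-room components in a PEPA-style stochastic process algebra, and
    analyses their performance. Pathway models are parsed from a small textual
    language or generated from department/resource configuration tables. The
    underlying continuous-time Markov chain is derived by reachability
    analysis, solved for its steady-state distribution, and lumped by a
    replica-counting abstraction; large populations are handled by a
    mean-field (fluid) ordinary-differential-equation approximation with
    minimum-rate coupling for shared activities. Resource utilisation,
    patient throughput, and passage-time distributions via stochastic probes
    are reported as tidy tables, with plotting helpers for sweep, saturation
    and passage-time results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Rcpp,
    Matrix,
    deSolve,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    readr,
    yaml
Config/testthat/edition: 3
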