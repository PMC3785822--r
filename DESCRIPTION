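Package: idtnet
Title: Information Dissipation Time of Units in Markov Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the dynamical importance of individual units in
    discrete-time Markov networks of binary (Ising) spins by their
    information dissipation time (IDT): the time it takes for the mutual
    information between a unit's instantaneous state and the evolving
    system state to fall below a small floor. Provides configuration-model
    network generation with power-law degree sequences, Glauber and
    Metropolis-Hastings spin simulation with a compiled core, exact and
    plug-in Shannon information estimators, an analytic IDT curve over
    node degree built from per-edge transmission information and the
    excess degree distribution, and an empirical IDT estimator driven by
    conditioned trajectory ensembles and regression, together with a
    command-line workflow for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
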