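Package: vtrial
Title: Virtual Intervention Trials in Degenerating Neural Mass Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a network of coupled alpha-rhythm neural masses on a
    human-connectome-like topology, degrades the network over virtual time by
    activity-dependent degeneration (ADD), and runs in-silico intervention
    trials in which neuronal excitability is raised or lowered globally or for
    excitatory/inhibitory populations selectively. Network health is tracked
    per degeneration cycle with spectral measures (relative lower-alpha power,
    peak frequency), phase lag index (PLI) functional connectivity, and graph
    topology of the functional network (normalized weighted clustering,
    modularity, algebraic connectivity, minimum spanning tree leaf number),
    plus structural normalized node strength. Conditions are compared to a
    healthy control with per-cycle t-tests and summarized as performance
    ratios against the untreated arm.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    signal,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
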