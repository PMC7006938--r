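Package: animats
Title: Evolution and Reliability of Markov-Brain Animats in Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the evolution of grid-world agents ("animats") whose
    behavior is controlled by genome-encoded Markov brains. Groups of clones
    navigate a two-room environment, earn rewards for gate crossings subject
    to a refractory period, and pay penalties for collisions. The package
    provides the genome encoding and mutation operators, deterministic
    Markov-brain assembly and transition-rule derivation, ASCII grid-world
    maps, a fast serial trial engine, a generation-based genetic algorithm
    without crossover, post-evolutionary reliability sweeps across group
    sizes and modified environments, behavior and state-transition analyses,
    and integrated-information (phi) brain-complexity measures computed by
    exhaustive partition search on small subsystems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
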