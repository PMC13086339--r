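Package: mealshare
Title: Individual Feed Ingestion Rates in Group-Reared Fish
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian analysis of individual feed ingestion rates in
    group-reared fish from per-pellet feeding-trial records. Implements a
    hierarchical multinomial softmax (discrete-choice) model in which each
    delivered pellet is consumed by one of the eight fish in a cage or
    wasted, with fixed effects of body surface, temperature or
    anthropogenic stress, diet level and delivered ration, and crossed
    fish- and trial-level random effects. Provides a seeded synthetic-data
    generator emulating a sea-cage feeding-trial design, Hamiltonian Monte
    Carlo estimation with convergence diagnostics, Pareto-smoothed
    importance-sampling leave-one-out model comparison, and the derived
    quantities used to describe feeding hierarchies: random-effect
    variance partition, individual meal shares, fish-specific effects,
    observed-versus-predicted pellet counts and clone-cage marginal-effect
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    coda,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    optparse
Config/testthat/edition: 3
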