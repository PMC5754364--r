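Package: accultdyn
Title: Acculturation Dynamics of Cultural Traits Under Continuous Migration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic implementations of a two-type
    cultural-evolution model of acculturation. A resident population
    receives a constant influx of immigrants carrying a different cultural
    trait; trait change is governed by each type's acculturation
    orientation (cultural conservatism and interaction tendency) and, when
    traits have payoff consequences, by success-biased social learning.
    Provides closed-form and numerical equilibrium analysis of the
    mean-field frequency dynamics (including coordination and
    complementation payoff regimes), an event-based individual-based
    simulator with exact one-event expectation oracles, parameter-sweep
    drivers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
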