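Package: fearsis
Title: Fractional-Order Predator-Prey Dynamics with Fear Effect and SIS
    Disease in Prey
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a Caputo fractional-order eco-epidemiological model in
    which a predator feeds selectively on infected prey, the prey population
    carries an SIS (susceptible-infected-susceptible) disease, and predator
    presence suppresses prey recruitment through a fear factor 1/(1+kP).
    Provides the model right-hand side and analytic Jacobian, a full-memory
    Adams-Bashforth-Moulton predictor-corrector integrator for Caputo
    initial-value problems, the one-parameter Mittag-Leffler function,
    closed-form equilibria (disease-and-predator-free, predator-free,
    co-existence) with the basic reproduction number, local stability
    classification via the Matignon condition and the fractional
    Routh-Hurwitz criterion, Lyapunov-derived global-stability predicates,
    forward and Hopf bifurcation threshold location, and parameter-sweep
    machinery with limit-cycle detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
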