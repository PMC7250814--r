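Package: frmech
Title: Mechanistic Derivation of Functional and Numerical Responses from
    Fast Behavioural-State Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving predator functional responses and prey and
    predator numerical responses from structured models of fast behavioural
    state transitions. Populations of prey and predators are divided into
    discrete behavioural states (e.g. exposed/hiding, searching/handling,
    well-fed/starving); transitions between states are fast relative to
    birth and death, so the state distribution equilibrates at fixed total
    densities and the population-level responses follow by time-averaging
    over the fast equilibrium. The package specifies and validates
    transition models, solves the fast-dynamics equilibrium (linear,
    triangular and fully coupled nonlinear cases), assesses hyperbolic
    stability and probes uniqueness, evaluates response surfaces, ships a
    zoo of closed-form applications (Holling type II and III, a generalized
    Beddington-DeAngelis response, density-dependent handling time, and a
    panic model inducing a predator Allee effect), simulates the full
    two-timescale system against the reduced Gause-type system, and
    provides JSON/CSV input-output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
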