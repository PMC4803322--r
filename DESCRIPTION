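Package: CompetenceCircuits
Title: Stochastic and Deterministic Models of the B. subtilis Competence Circuits
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models of the Bacillus subtilis competence decision circuit and of a
    synthetic analog (SynEx) in which ComK activates its own repressor MecA.
    Implements the two-species chemical master equation for each circuit with a
    sparse steady-state solver, exact Gillespie simulation, the mean-field
    deterministic limit with fixed-point and regime-boundary analysis
    (excitable / oscillatory / mono-stable), the responsive-fraction statistic f
    computed by inflection-point and two-Poisson-mixture methods, viable-response-
    range expansion factors, power-spectrum diagnostics for noise-induced
    oscillations, and a cumulative-distribution fit that maps fluorescence
    intensity distributions to model induction rates. A synthetic-data generator
    emulates fluorescence titration experiments so the full fitting pipeline is
    testable without microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    Matrix,
    deSolve,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
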