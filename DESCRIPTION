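Package: fsvlf
Title: Fractional Vieta-Lucas Spectral Collocation for Singular Nonlinear
    Multi-Order Boundary Value Problems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves singular, strongly nonlinear, multi-order fractional
    two-point boundary value problems by matrix collocation in a basis of
    fractional-order shifted Vieta-Lucas functions, with the nonlinearity
    handled by quasilinearization (Newton-type iteration on linearized
    subproblems).  The motivating application is the steady-state
    Liouville-Caputo fractional heat-conduction model of the human head,
    where a singular coefficient A/r and an exponential metabolic heat
    source make the problem analytically intractable.  Provides the basis
    machinery (values, explicit monomial coefficients, roots, weighted
    projections, theoretical error bounds), Caputo power-rule derivative
    rows, the iterated collocation solver with boundary-row substitution,
    residual-error diagnostics with numerical convergence orders, and
    scripted reproduction of benchmark parameter studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
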