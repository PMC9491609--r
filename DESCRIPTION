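Package: hemigait
Title: Predictive Simulation of Hemiparetic Gait by Direct Collocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Solves periodic optimal-control gait problems for a sagittal-plane
    musculoskeletal model (11 degrees of freedom, 24 Hill-type muscle-tendon
    units with implicit tendon compliance) under graded unilateral muscle
    weakness, using Hermite-Simpson direct collocation transcribed to a
    nonlinear program and solved with an augmented-Lagrangian method. Reports
    emergent step-length and step-time asymmetry, metabolic cost of transport
    (Umberger and Bhargava muscle energetics), and positive/negative mechanical
    work, and provides smooth step-length/step-time symmetry objective terms
    for enforcing spatiotemporal symmetry. Includes a synthetic normative
    reference-gait generator used to seed tracking optimizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
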