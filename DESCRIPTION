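Package: cometpool
Title: Actin Turnover Kinetics of Bead-Propelled Comet Tails in Closed Microwells
Version: 0.1.0
Authors@R: person("Comet", "Maintainers", email = "cometpool@example.org",
    role = c("aut", "cre"))
Description: Compartmental kinetic model of a limited actin-monomer pool driving
    bead-propelled comet-tail motility in sealed cell-sized microwells. Provides
    the three-pool turnover ODE system (tail F-actin, ADP-G-actin, ATP-G-actin)
    with optional non-tail assembly and monomer aging, its analytic dynamic
    steady state, calibration of rate constants from observable velocity and
    tail-length ratios, least-squares fitting of kinetic parameters to comet
    tracks, trajectory statistics (motility half-life, cumulative polymerized
    length, monomer-pool cycle counting, consumption rate, defect-decay
    disassembly constants), order-of-magnitude molecular estimates for the
    microwell compartment, and a seeded generator of synthetic comet tracks and
    defect traces for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
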