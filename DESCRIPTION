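Package: aidkit
Title: Simulation and Single-Cell Analysis of Auxin-Inducible Degron Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of single-cell fluorescence trajectories of
    degron-tagged reporters under auxin perturbation schedules in budding
    yeast, together with estimators for protein depletion rate, depletion
    completeness and its autofluorescence floor, intercellular variability,
    mother-daughter depletion asymmetry, cell-cycle-resolved dilution factors
    from sawtooth recovery traces, and growth-rate perturbation and recovery.
    Includes constrained dose-response fits (two-phase exponential decay,
    fixed-asymptote log-logistic), smoothing-spline derivative estimation,
    nonparametric bootstrap confidence intervals, and division-cycle
    segmentation from budding events.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
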