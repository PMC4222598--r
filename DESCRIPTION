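Package: ischvf
Title: Ventricular Fibrillation Dynamics Under Global Cardiac Ischemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale simulation and analysis of human ventricular
    fibrillation under global cardiac ischemia. Implements the ten Tusscher-
    Panfilov 2006 (TP06) epicardial ventricular cell model extended with an
    ATP-sensitive potassium current, a three-component ischemia
    parameterization (hyperkalemia, acidosis, hypoxia), a monodomain
    reaction-diffusion solver for 1D cables and 2D sheets, S1S2 action
    potential duration and conduction velocity restitution protocols,
    dominant-frequency and phase-singularity analysis of fibrillatory
    activity, and an inverse procedure that estimates extracellular potassium
    and ATP-channel activation trajectories from dominant-frequency
    recordings. Ships deterministic synthetic-data generators (patient-like
    dominant-frequency recordings with known ground truth, planted vortex
    phase fields, fibrillation initial states) so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
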