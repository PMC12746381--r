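Package: gradstim
Title: Cardiac Magnetostimulation Safety Ratios for MRI Gradient Coils
Version: 0.1.0
Authors@R: person("Gradstim", "Developers", email = "gradstim@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation pipeline for cardiac magnetostimulation
    safety analysis of MRI gradient systems. Generates synthetic voxel torso
    phantoms with myocardium, blood pool and lung compartments; models
    gradient coils as wire-loop sets with exact finite-segment Biot-Savart
    fields and vector potentials; solves the magneto-quasistatic scalar
    potential problem on heterogeneous conductivity grids to obtain induced
    electric fields; computes percentile-based myocardial E-field metrics
    (Emax, E99.9, E99, E95) that mitigate voxel staircasing artifacts;
    orchestrates landmark sweeps producing dB/dt-over-E-field conversion
    ratios over the IEC 60601-2-33 compliance volume; and evaluates the
    log-normal population threshold model behind the IEC cardiac dB/dt limit,
    including adverse-event probabilities and strength-duration limit curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
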