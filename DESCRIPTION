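Package: qscrosstalk
Title: Neural-Network Models of Quorum-Sensing Crosstalk in Multi-Strain
    Bacterial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses quorum-sensing (QS) signal crosstalk in
    communities of Bacillus subtilis strains that produce chemical variants of
    the ComX peptide pheromone. Gene expression of a QS-regulated LacZ reporter
    is modelled with Hill-function ordinary differential equations coupled to
    logistic growth, and crosstalk between signal variants is captured by a
    single-layer neural network: each strain senses a clamped weighted sum of
    all signal concentrations. The package provides a forward finite-difference
    simulator, dose-response curve fitting by RMSE minimisation, inversion of
    binary activation landscapes into crosstalk-weight intervals, prediction of
    community-level binary signaling states, co-culture dynamics with
    inoculation-ratio sweeps and timed signal perturbations, and a synthetic
    data generator emulating plate-reader measurements with known ground truth.
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
RoxygenNote: 7.3.3
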