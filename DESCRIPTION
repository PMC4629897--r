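Package: AtriaSim
Title: Multiscale Simulation of Human Atrial Electrophysiology and Body-Surface Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiscale simulator of human atrial electrical activity and its
    body-surface signature. Provides regionally heterogeneous human atrial
    myocyte models (Maleckar-type) with pacing and stability diagnostics,
    anisotropic monodomain reaction-diffusion propagation on hexahedral meshes
    with fibre fields built from regional principal directions,
    conduction-velocity calibration of equivalent conductivities in tissue
    slabs, forward computation of extracellular potentials (infinite-medium
    pseudo-ECG integral and a heterogeneous-torso Laplace solve), and derived
    signal analyses: local activation time and APD maps, body-surface RMS
    maps, P-wave morphology features and per-region source-contribution
    decomposition.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
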