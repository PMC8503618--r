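Package: afpathways
Title: Preferential Activation Pathway Mapping for Atrial Fibrillation
    Basket Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Time-averaged wavefront analysis for multi-electrode atrial
    recordings. Processes raw unipolar electrograms from 64-electrode
    basket catheters into normalised filtered derivative signals, arranges
    them on a 2D anatomical grid, estimates per-frame activation flow with
    Horn-Schunck optical flow, averages flow vectors at detected
    wavefronts over 10 s windows, extracts preferential-pathway
    streamlines, and computes the pulmonary-vein (PV) activation flow
    metric used to discriminate acute responders from non-responders to
    pulmonary vein isolation. Includes a kinematic synthetic activation
    generator (planar, rotor, focal, multi-wavelet drivers), cohort
    statistics, and scripted sensitivity experiments (recording window,
    electrode dropout, grid variant).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
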