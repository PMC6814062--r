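Package: osteotherm
Title: Simulation of MR-Guided Focused Ultrasound Hyperthermia in
    Osteolytic Bone Lesions
Version: 0.1.0
Authors@R:
    person("Imaging", "Therapy Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator for mild hyperthermia of osteolytic bone
    lesions by high-intensity focused ultrasound (HIFU) through the natural
    acoustic window of a cortical breakthrough. Builds voxelized bone/lesion
    phantoms, computes the focused pressure and intensity field of a
    spherical-cap transducer (Rayleigh-Sommerfeld integral), converts it into
    the dual heat source (direct focal absorption plus the "acoustic oven"
    surface-averaged cortical term), propagates temperature by iterative
    Gaussian-kernel diffusion, emulates PRFS MR thermometry (noise, drift,
    signal voids) and an intracortical fluoroptic sensor, and closes the loop
    with a predictive duty-cycle temperature controller. Includes time-lag
    surface analysis, focal-offset studies and session-level reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
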