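Package: sonocal
Title: Acoustic-Emission-Calibrated Focused Ultrasound Exposure Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for microbubble-mediated focused
    ultrasound blood-brain-barrier opening with acoustic-emissions-based exposure
    calibration. Generates multichannel RF burst captures from a sparse hemispherical
    receiver array, forms 3D passive cavitation images by delay-and-sum beamforming
    of ultraharmonic emissions, detects inertial cavitation from band-integrated
    subharmonic-receiver spectra, runs the closed-loop pressure-ramp calibration
    controller with retrospective quality-control exclusion rules, quantifies
    relative gadolinium contrast enhancement and immunofluorescence in synthetic
    image volumes, and provides the outcome statistics and treatment-capacity
    planning used to evaluate sonication parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    RNifti,
    car,
    emmeans,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
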