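Package: aperspectra
Title: Biophysical Modelling and Detrending of Aperiodic EEG Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing the aperiodic (broadband)
    component of EEG power spectra. Implements Lorentzian spectral-trend
    models grounded in synaptic kinetics, a FOOOF-style peak-plus-trend
    fitter with divisive and subtractive detrending, a point-dipole
    conductance-based neuron simulator with Poissonian and rhythmic synaptic
    drive, a spatial subcritical branching network with spike-time tiling
    correlations, spherical-embedding machinery for dipole coherence,
    ensemble EEG power estimation on cortical meshes, a multitaper
    spectrogram pipeline for propofol induction recordings (effect-site
    pharmacokinetics, Hill dose-response, detrended band power), and a
    synthetic-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
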