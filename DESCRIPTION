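Package: smmds
Title: Single-Molecule Microfluidic Diffusional Sizing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for single-molecule microfluidic diffusional
    sizing (smMDS) experiments. Converts photon timestamp traces recorded
    across a microfluidic sizing chip into calibration-free hydrodynamic
    radii via simulated advection-diffusion basis profiles, detects
    single-molecule bursts with a combined inter-photon-time and
    minimum-photon-count criterion, deconvolves oligomeric states from
    burst-brightness histograms, separates and sizes rare large species
    (fibrils, nanoscale condensate clusters) in mixed traces, extracts
    binding affinities from size-based isotherms, and ships a physics-based
    synthetic-data generator so every stage of the pipeline can be validated
    against ground truth without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
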