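Package: speckperf
Title: Speed-Resolved Perfusion from Multi-Exposure Laser Speckle Contrast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation-trained estimation of speed-resolved microcirculatory
    perfusion in absolute units (%RBC x mm/s) from multi-exposure laser speckle
    contrast. Implements a physics forward model (Monte Carlo photon transport
    in a three-layer skin model, Doppler power-spectrum composition with a
    Gegenbauer-kernel phase function and vessel packaging, Wiener-Khinchine
    speckle decorrelation, a biological-zero component and a contrast noise
    model) that maps randomized tissue models to squared speckle contrast at
    seven exposure times, and a small feed-forward neural network trained on
    that synthetic corpus that inverts contrast curves to perfusion in the
    speed bands 0-1, 1-10 and >10 mm/s. Includes per-pixel image inference,
    synthetic image fixtures, parameter-sweep drivers and evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
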