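Package: tbfit
Title: Forward-Optimization Inversion of Ultrafast Scattering Data in a
    Trajectory Basis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Inverts time-resolved pump-probe X-ray scattering and electron
    diffraction data by fitting a weighted ensemble of semiclassical
    trajectories to the experimental percent-difference signal. Implements
    rotationally averaged independent-atom-model (Debye) scattering for
    X-ray and electron probes, the apparatus mapping (excitation fraction,
    Gaussian instrument-response convolution, time-zero shift, temporal
    binning), a confidence-weighted least-squares objective, Monte-Carlo
    initialized bound-constrained weight optimization with global-parameter
    scans, a two-step procedure for noisy data, fit-quality metrics, and a
    synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
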