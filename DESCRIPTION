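Package: larvosc
Title: Analysis of the C. elegans Larval Gene-Expression Oscillator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterize the oscillatory gene-expression
    program of C. elegans larval development. Implements fixed-period cosine
    regression with error-propagated amplitude confidence intervals to classify
    oscillating genes; Butterworth band-pass filtering and Hilbert-transform
    quantification of instantaneous phase, angular velocity and period;
    time-point correlation analysis with spline-based peak detection, cycle-phase
    assignment and arrest-phase identification; breakpoint estimation for the
    embryonic onset of oscillations; phase-locking statistics coupling molting to
    the oscillator in single-animal reporter traces; molt detection from
    luciferase luminescence; a two-parameter (supercritical Hopf / SNIC)
    bifurcation simulator; and synthetic-data generators with known ground truth
    for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    deSolve,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
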