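Package: nvodmr
Title: Simulation and Analysis of CW-ODMR Spectra for Nitrogen-Vacancy Magnetometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of continuous-wave optically detected magnetic
    resonance (CW-ODMR) spectra of nitrogen-vacancy (NV) centers in diamond --
    single centers, oriented bulk ensembles, and randomly oriented nanodiamond
    powders -- under an applied magnetic field, together with the spectral
    analysis chain used to read magnetic fields back out: expectation-
    maximization background subtraction, moving-average smoothing, natural
    cubic-spline resampling, dip detection with parabolic refinement, double-
    Lorentzian fitting, Zeeman-splitting field estimation, gyromagnetic-ratio
    calibration, and sweep-resolution planning for nanotesla-scale biosensing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
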