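Package: classao
Title: Computational Adaptive Optics for Time-Gated Reflection Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and correction of sample-induced optical aberrations
    in time-gated reflection-matrix microscopy. Synthesizes angle-scanned
    complex reflection data and rotating-reference off-axis interferograms
    from ground-truth specimens and pupil phase screens, demodulates
    interferograms back to laboratory-frame fields, and recovers
    position-dependent input and output pupil aberrations by closed-loop
    accumulation of single scattering (CLASS): iterative per-mode phase
    updates that maximize the total intensity of the confocal (diagonal)
    image. Includes tile-wise correction for field-varying aberrations,
    point-spread-function and Strehl-ratio metrology, angular-spectrum
    numerical refocusing, volumetric stacking with maximum-intensity
    projections, and a scriptable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
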