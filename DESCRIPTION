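Package: phycomon
Title: Simulated Photobioreactor Fluorescence Monitoring of Cyanobacteria
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A virtual photobioreactor with an in-line fluorescence
    spectrometer for monitoring phycocyanin in cyanobacterial cultures.
    Implements an optical forward model (LED excitation, pigment emission,
    density-dependent scattering, detector noise and saturation), the
    dual-exposure acquisition protocol with excitation-peak scattering
    normalization, culture dynamics for growth, photoinhibition and
    contamination scenarios, and analytics: trend classification from
    joint optical-density and fluorescence series, excitation-LED
    selection, and limit-of-detection estimation from calibration series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
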