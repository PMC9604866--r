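Package: sarcmi
Title: SAR-Guided Confocal Microwave Imaging for Breast Tumor Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and image reconstruction toolkit for ultra-wideband
    confocal microwave imaging (CMI) of the breast. Implements a hemispherical
    breast phantom with configurable tissue dielectrics, a Gaussian-monocycle
    excitation pulse, a point-scatterer monostatic backscatter simulator, tumor
    pre-localization from the specific absorption rate (SAR = sigma*E^2/rho),
    reduced-aperture antenna placement planning around the SAR maximum, and
    delay-and-sum (DAS) synthetic-focusing reconstruction with calibration and
    row-average clutter removal, together with image quality metrics and
    scripted comparison scenarios against a conventional full-ring scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
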