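Package: crDoppler
Title: Complex-Regression Doppler Optical Coherence Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phase-shift estimation for Doppler optical coherence tomography (OCT)
    from densely sampled complex M-scans and B-scans. Implements the conventional
    two-point (Kasai autocorrelation) estimator with N-average variants and a
    multipoint complex-regression estimator that realigns A-lines in polar
    coordinates and minimizes the dispersion of the realigned points, extending
    the velocity dynamic range without phase wrapping. Includes analytic
    dynamic-range and detection-floor calculators, a capillary-tube flow-phantom
    simulator with SNR-calibrated phase noise, an evaluation protocol for
    minimum-detectable-velocity studies, complex averaging for structural images,
    scan container input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    optparse,
    tiff,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'core.R'
    'estimators.R'
    'phantom.R'
    'evaluation.R'
    'plots.R'
    'io.R'
    'cli.R'
    'crDoppler-package.R'
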