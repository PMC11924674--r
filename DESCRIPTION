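Package: neuroraman
Title: Fiber-Optic Raman Spectral Preprocessing and Intracranial Tissue Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for single-point fiber-optic Raman spectroscopy of intracranial
    tissue. Implements the full conditioning chain from raw CCD accumulation frames
    to a normalized spectral fingerprint (dark-count subtraction, cosmic-ray removal,
    wavenumber calibration against an acetaminophen reference, instrument-response
    correction, rolling-bubble baseline removal, Savitzky-Golay smoothing, truncation
    to the 800-1800 cm-1 fingerprint region and standard-normal-variate scaling),
    a signed-energy quality factor for gating low-quality acquisitions, spectral
    angle mapper similarity analyses, and a two-stage sparse linear support vector
    machine classifier (L1 feature selection to fewer than 20 spectral bins followed
    by an L2 decision stage) evaluated with subject-disjoint train/test splits.
    A seeded synthetic-data generator emulates a nine-tissue sellar-region dataset
    so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    signal,
    glmnet,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
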