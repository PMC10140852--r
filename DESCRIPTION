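Package: decellmon
Title: Optical Monitoring and Endpoint Detection for Organ Decellularization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring perfusion-based organ decellularization and
    detecting its endpoint. Provides a Beer-Lambert optical phantom of a
    dye-filled simulated heart under constant-flow dilution, an image-based
    process-variable monitor (ROI mean grayscale, percentage scaling,
    Gaussian smoothing, last-N/k-percent stopping rule), a
    successive-differences plateau detector for spectrophotometric
    concentration series (DNA, protein, dye), and control-versus-treatment
    comparison of decellularization times. All inputs can be generated
    synthetically, so the full pipeline is testable without laboratory
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
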