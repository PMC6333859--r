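Package: epikinet
Title: Kinetic Modelling and Asymmetry Statistics for Dynamic FDG-PET
    Lateralization of Epileptic Foci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits the irreversible two-tissue compartment model to regional
    dynamic FDG-PET time-activity curves using a carotid image-derived input
    function corrected for partial-volume effects (recovery coefficient and
    spill-in estimated from the scanner point-spread function), derives the
    net metabolic flux Ki = K1*k3/(k2+k3), computes side-to-side asymmetry
    indices for kinetic micro- and macro-parameters and for static activity
    concentration, and runs the rank-based group statistics used to
    characterize hypometabolic epileptogenic regions. A synthetic-cohort
    generator produces bolus input functions, noisy frame-averaged tissue
    curves under a multi-group dynamic frame protocol, carotid measurements with
    controllable recovery/spill-in mixing, and late-window static scans with
    controllable true asymmetry, so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
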