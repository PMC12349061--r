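Package: copsplit
Title: Per-Foot Ground Reaction Force and Centre of Pressure from a Single Forceplate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering the vertical ground reaction force and
    centre-of-pressure trajectory of each foot during bipedal stance when
    only a single forceplate is available. Implements an analytical split of
    the global centre of pressure based on fixed foot placement and a
    mediolateral load factor, the forceplate signal-processing chain (tare,
    zero-phase Butterworth low-pass filtering, squat-trigger trimming),
    centre-of-pressure computation from four uniaxial corner sensors together
    with its exact bilinear inverse, stabilometry error metrics (RMSE, NRMSE,
    Pearson correlation), a postural-sway trial simulator with known per-foot
    ground truth, and small multilayer-perceptron regression models trained
    with Levenberg-Marquardt as a data-driven alternative to the analytical
    split.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite,
    rlang,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
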