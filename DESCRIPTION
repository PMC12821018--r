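Package: forcemap
Title: Elasticity Mapping from AFM Force-Distance Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy (AFM) indentation
    of soft tissue with large spherical probes: Hertz and Sneddon contact
    models, contact-point detection and apparent reduced elastic modulus (K)
    fitting for force-distance curves, spatial elasticity maps with
    gray/white-matter compartment statistics (per-map medians and the
    gray-to-white stiffness ratio), postmortem time-course binning, and
    temperature regression with extra-sum-of-squares model comparison.
    Includes a synthetic force-curve and tissue-phantom generator that
    emulates the measurement physics, so every pipeline stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
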