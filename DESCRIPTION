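Package: gelrelax
Title: Stress-Relaxation Analysis of Soft Hydrogels by Generalized
    Maxwell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing low-load compression stress-relaxation
    tests of soft biomaterial hydrogels such as decellularized
    extracellular-matrix gels.  Reads instrument traces, detects
    plunger-gel contact, converts force and deformation to stress and
    strain, extracts instantaneous stiffness and the relaxing-stiffness
    curve, fits generalized Maxwell (Prony-series) models with
    chi-squared-driven model-order selection, computes relative
    importances of Maxwell elements, flags collapsed gels, and aggregates
    replicate measurements into donor and cohort summaries.  Includes a
    forward simulator of the compression experiment so parameter-recovery
    tests can stand in for unavailable laboratory data.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
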