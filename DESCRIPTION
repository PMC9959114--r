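Package: electrobend
Title: Bending Rigidity of Free-Standing Planar Lipid Bilayers from
    Voltage-Dependent Capacitance
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Determines the Young's modulus, area-expansion modulus and
    bending rigidity of free-standing planar lipid bilayers (black lipid
    membranes and large-area model biomembranes) from simultaneous
    capacitance, area and voltage measurements under a square-wave
    voltage-clamp protocol.  Implements the constant-volume capacitance
    correction that separates electrostrictive thinning from voltage-driven
    area growth, thin-plate conversion of the Young's modulus to an
    area-expansion modulus and bending rigidity, a forward simulator of the
    full measurement for validation, and bookkeeping for asymmetric-ion
    dilution series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
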