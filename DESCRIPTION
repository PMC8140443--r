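Package: carecycle
Title: Cyclical Continuum-of-Care Modeling for Health-Disparity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building cyclical (circular) continuum-of-care models
    from electronic health record style cohort tables. Provides declarative
    continuum definitions (phases, elements, classification rules), rule-based
    phenotyping of diagnosis, lab, medication and procedure events into a
    patient-by-element indicator matrix, stratified age- and sex-adjusted
    odds-ratio estimation with a lowest-crude-odds reference-group convention,
    deterministic radar-style visualization of the continuum on a natural-log
    scale, and a seeded synthetic-cohort simulator with known ground truth so
    every stage of the pipeline can be validated end to end without patient
    data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
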