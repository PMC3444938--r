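Package: silacdyn
Title: Pulsed-SILAC Proteome Dynamics and Isotope-Tracer Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pulsed stable-isotope labeling
    (pulsed SILAC) experiments in slow-growing photosynthetic cells.
    Estimates per-protein degradation rates and half-lives from
    heavy/light ratio time courses with an explicit correction for
    growth dilution, ranks relative protein abundance by an
    intensity-per-mass abundance index, compares relative synthesis
    rates across stress conditions via Z-normalized ratios, and
    quantifies percent 13C label incorporation into free metabolites
    from GC-MS fragment mass-isotopomer pairs.  Includes seeded
    synthetic-data generators with ground-truth tables so every stage
    is testable without raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
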