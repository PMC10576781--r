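Package: pimsr
Title: Single-Ion Proteoform Imaging Mass Spectrometry Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for processing individual-ion (charge detection) mass
    spectrometry data from proteoform imaging experiments: charge assignment
    from STORI slopes, kernel-density mass-domain spectra with iterative
    feature picking, in-silico precursor purification and isolation-window
    scoring for data-dependent MS2, spatial bin allocation of targets along
    a probe line scan, chronological acquisition-method export,
    region-of-interest label-free quantitation with Benjamini-Hochberg
    filtering and PCA, proteoform image reconstruction, and intact-mass-tag
    annotation against a protein database with PTM combinations. Includes a
    fully seeded synthetic single-ion data generator so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
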