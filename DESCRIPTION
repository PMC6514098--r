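Package: azfcnv
Title: MLPA Copy-Number Calling and Case-Control Association for
    Y-Chromosome AZF Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and classifying copy-number variants
    (deletions, duplications and complex deletion+duplication events) in the
    azoospermia factor (AZF) regions of the human Y chromosome from multiplex
    ligation-dependent probe amplification (MLPA) peak areas.  Peak areas are
    normalized against reference samples, per-probe copy states are called
    with a 30 percent relative-dosage rule, and call patterns are matched
    against a catalogue of 24 AZF rearrangement classes, with DAZ1/2 versus
    DAZ3/4 composition resolved from sY587 restriction-digest band
    intensities.  The package also predicts presence/absence patterns for the
    ten EAA/EMQN sequence-tagged-site markers, performs delta-delta-Ct qPCR
    relative quantification, computes case-control association statistics
    (odds ratios with Wald intervals, chi-squared and Fisher's exact tests),
    and ships a seeded synthetic-cohort simulator so the whole pipeline can
    be exercised without access to raw capillary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
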