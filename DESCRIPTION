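Package: mdvflux
Title: Quality Control and Isotope Correction of Mass Isotopomer
    Distributions for Metabolic Flux Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing of stable-isotope labeling data measured by GC-MS or
    LC-MS ahead of 13C metabolic flux analysis.  Reads tab-separated
    intensity matrices of mass isotopomer distribution vectors (MDVs),
    performs pre-correction quality checks (missing values, detector range,
    retention-time outliers), corrects MDVs for naturally occurring stable
    isotopes, proton loss or gain during ionisation, and dilution by
    unlabeled original biomass, computes average-labeling diagnostics,
    aggregates biological replicates, and exports measurement sections for
    downstream flux-analysis software (13CFLUX FTBL, OpenFLUX CSV).  A
    forward-model simulator generates synthetic datasets with known ground
    truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
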