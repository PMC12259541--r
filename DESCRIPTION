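Package: hostrange
Title: Host-Preference Curation and Specificity Analysis for Holoparasitic Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating and analysing host-preference records of
    holoparasitic plants. Provides a rule-based three-tier confidence rating
    for host records, contextual filtering to build an analysis set,
    per-parasite host-specificity profiles at species, genus and family rank,
    host-side convergence statistics across independent parasite lineages,
    extent-of-occurrence areas from occurrence coordinates, and
    phylogeny-ordered parasite-by-host interaction matrices. A synthetic-data
    generator with known ground truth makes every stage of the pipeline
    testable without access to the underlying record database.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    withr
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
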