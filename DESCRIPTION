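Package: arachnotrade
Title: Detecting and Quantifying the Arachnid Trade from Web Corpora and
    Trade Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for monitoring wildlife trade in arachnids (spiders,
    scorpions, whip scorpions) across heterogeneous sources. Builds a
    species/synonym name index from taxonomic checklists, cleans saved web
    pages into searchable text, runs a hierarchical genus-then-species
    fixed-string keyword search with context capture and spurious-genus
    filtering, quantifies colour terms co-occurring with genus mentions,
    classifies LEMIS and CITES trade records (whole-individual filtering,
    wild/captive sourcing, commercial purpose, seizures), integrates
    species lists across sources (overlaps, per-year trends,
    description-to-trade lags, per-site richness), and digitises textual
    range assertions into country-level presence for endemism and
    trade-exposure summaries. Includes seeded synthetic-data generators
    with recorded ground truth so the whole pipeline is testable offline.
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
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tools,
    utils,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
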