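Package: nichecontrast
Title: Sister-Group Contrasts of Climatic and Edaphic Niches Across
    Photosynthetic Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing the climatic and soil niches of plant
    lineages differing in photosynthetic type (C3, C3-C4 intermediate, C4)
    using georeferenced occurrence records.  Provides occurrence-record
    quality control (coordinate validation, land-mask filtering,
    institution-proximity filtering, coordinate-rounding deduplication),
    extraction of environmental variables from regular latitude/longitude
    rasters, derivation of bioclimatic summaries from monthly stacks
    (wettest-quarter temperature, coldest-month minimum, driest-month
    precipitation, rainfall seasonality), correlation-matrix principal
    component analysis, per-species median and per-group mean-of-medians
    niche aggregation, Whittaker-style biome classification, and two
    sister-group inference procedures: Kendall rank correlation between
    sister lineages and a two-tailed binomial sign test of directional
    niche shifts with a multiple-testing-corrected threshold.  A fully
    deterministic synthetic-data generator (environment grids, lineages
    with tunable niche conservatism, error-laden occurrence records with
    ground truth) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
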