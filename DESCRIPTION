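Package: eegcostnet
Title: Economical Small-World Analysis of EEG Functional Cortical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Band-specific functional cortical network analysis for multichannel
    EEG: mutual-information association matrices of Morlet wavelet band series,
    cost-thresholded binary graph ensembles, global/local/nodal efficiency,
    cost-efficiency and small-worldness against matched random and regular null
    models, and cohort-level statistics (per-cost two-way ANOVA, Z-scored nodal
    maps with tiered significance, duration-of-disease correlations). Includes a
    seeded synthetic-cohort generator with planted group-by-condition coupling
    effects so the full pipeline is testable without recorded EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
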