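Package: metaltol
Title: Comparative Analysis of Heavy-Metal Tolerance Across Butterfly Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating butterfly species' heavy-metal tolerance to
    geographic range size and evolutionary history with mutagenic host
    plants. Compiles methodology-corrected mutagenicity scores for plant
    families from Ames-test records, weights them by larval host use into a
    per-species mutagenicity index, estimates species-level metal-tolerance
    proxies from left-censored tissue concentrations by maximum likelihood,
    computes geographic range areas from habitat-suitability rasters on a
    spherical Earth, and fits phylogenetic generalized least squares models
    with maximum-likelihood Pagel's lambda. Includes a synthetic-data
    generator with known ground truth for every pipeline input, and an
    end-to-end pipeline producing the species analysis table and per-metal
    model reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    nlme,
    phytools,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
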