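Package: minecore
Title: Core Microbiota, Niche Breadth and Assembly Stochasticity from OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream community-ecology analysis for amplicon OTU tables
    from paired habitats (e.g. mine drainage and surrounding soil):
    occupancy-abundance classification of habitat generalist and specialist
    OTUs at a relative-abundance threshold, extraction of the core
    microbiota and its taxonomic composition, a Bray-Curtis null model with
    a PERMDISP test for stochastic versus deterministic community assembly,
    and Spearman rank-correlation screening of OTUs against geochemical
    parameters with exact permutation p-values at small sample sizes.
    Includes a synthetic community generator with planted, recorded ground
    truth so every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
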