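Package: glyconet
Title: Automated Construction and Analysis of Glycosylation Reaction Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-readable definitions of glycosyltransferases and
    glycosidases drive single-step reaction inference and automated
    reconstruction of whole glycosylation reaction networks (forward,
    reverse and connection inference). Glycans are rooted ordered trees
    with LINUCS- and GlycoCT-style text encodings; constructed pathways
    support graph-theoretic analysis (exhaustive path finding, subset
    network generation, isolated-species handling), export to SBML with
    embedded structure annotations, and DOT/GraphML graph export.
    Includes MALDI-TOF glycomics helpers: spectrum ingestion, four-step
    peak processing (baseline adjustment, normalization, noise removal,
    peak finding), permethylated-composition annotation and a seeded
    synthetic-spectrum generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
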