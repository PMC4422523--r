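Package: circanet
Title: Multi-Evidence Expansion of Circadian Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a network of circadian regulated genes by expanding a
    curated core-clock seed network with several independent evidence layers:
    mutual-rank co-expression target prediction with tightness filtering,
    aggregation of literature-mined interaction tables, hypergeometric term
    overrepresentation with Benjamini-Hochberg correction, ChIP-seq
    closest-gene target calling, and a rank-based circadian rhythmicity scan.
    Ships a synthetic-data generator with known planted truth so the whole
    pipeline is testable end-to-end without external downloads, plus layered
    network assembly with per-edge provenance and GraphML/SIF export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    mclust
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
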