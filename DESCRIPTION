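Package: promoterforge
Title: High-Throughput Gateway Promoter-Reporter Primer Design and Construct Tracking
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for batch production of promoter-reporter (GFP) constructs
    in Arabidopsis-scale projects. Selects candidate genes from Affymetrix
    present/marginal/absent call matrices with an MPSS exclusion, extracts
    3000 bp upstream + 150 bp downstream promoter templates around the
    translation start, designs Gateway-compatible primer pairs under
    product-size and placement constraints with nearest-neighbor melting
    temperatures, screens primer specificity genome-wide at 80 percent
    identity with a brute-force oracle and a seeded fast path, appends attB
    recombination tails and emits 96-well plate order files, and tracks
    constructs through the transformation funnel with Plant Ontology (PO)
    expression-annotation summaries and queries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
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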