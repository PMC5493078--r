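Package: supersage
Title: Deep SuperSAGE Tag-Based Differential Expression Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Digital gene expression profiling with 26-nt SuperSAGE tags
    for a 2x2 bulked-segregant design (cold acclimation x frost
    tolerance). Provides ditag deconvolution and tag extraction at the
    NlaIII (CATG) anchor, unitag counting and tags-per-million
    normalization, the Audic-Claverie exact test with coefficient-of-
    variation and abundance filters, classification of tags into
    exclusive and over-represented sets, anchored tag-to-reference
    matching with antisense strand calls, summary reporting, and a
    seeded synthetic-data generator with planted effects so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
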