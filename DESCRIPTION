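Package: embryoevo
Title: Stage-Specific Coexpression Modules and Evolutionary Conservation
    in Preimplantation Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects stage-specific gene coexpression modules in human
    preimplantation embryo RPKM expression profiles via a weighted
    coexpression network (soft-threshold adjacency, topological overlap,
    dynamic hybrid tree cut, eigengene merging), assigns modules to
    developmental stages through eigengene-indicator correlation, and
    scores each stage's gene set with four evolutionary conservation
    indices: a median dN/dS resampling test, gene-age interval enrichment,
    human-zebrafish ortholog-class enrichment, and transcription-factor /
    conserved-noncoding-element promoter enrichment, summarized into a
    per-stage conservation trend. Includes a seeded synthetic-data
    generator with planted module and conservation structure so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
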