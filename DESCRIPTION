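Package: denovoscreen
Title: De Novo Variant Filtration, Burden Testing and Structural Variant
    Consensus for WGS Trio Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for whole-genome-sequencing trio
    studies of rare disease: staged de novo small-variant filtration
    (trio intersection, quality, rarity, functional class, damaging
    predictions) and Mendelian inheritance-model screening with ACMG
    evidence combination; gene-wise case/control damaging-variant burden
    testing with Fisher exact tests and a resampled gene-set null;
    multi-caller CNV/SV consensus by reciprocal overlap with de novo
    determination and breakpoint-junction microhomology and
    templated-insertion characterization; and stratification of de novo
    variants in possible regulatory regions with candidate-gene and
    topological-domain co-localization filters. Seeded generators produce
    every input with truth tables, so the full pipeline is testable on
    synthetic trios and cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
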