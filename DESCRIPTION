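Package: somaclone
Title: Somatic Polymorphism Discovery Among Vegetatively Propagated Clones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genome-wide comparison of
    vegetatively propagated plant clones from long-read pyrosequencing data.
    Generates repeat-rich synthetic clone genomes with a ground-truth mutation
    ledger, simulates 454-style reads, performs tiered seed-and-extend
    alignment with read classification, coverage-gated calling of somatic
    SNPs, indels and transposable-element insertion polymorphisms, in-silico
    S-SAP banding with Nei-Li distances and neighbor-joining trees, and LTR
    retrotransposon form clustering to index recent element activity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    ape,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
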