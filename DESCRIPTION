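Package: spidroinr
Title: Spidroin Gene Discovery and Silk Composition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and annotation of spider silk protein (spidroin) genes
    from a genome and proteome: homology search against terminal-domain
    references with Karlin-Altschul E-values, tandem-repeat detection by
    self-alignment periodicity, silk motif grammar quantification (poly-A,
    (GA)n, GGX, GPGXX, XQQ), genomic gene-model reconstruction with
    frameshift-aware repair, type classification and chromosomal grouping,
    gland expression profiling (FPKM, tau specificity, silk transcriptional
    load), and dragline-silk proteome/metabolome bookkeeping (tryptic digest,
    iBAQ shares). Includes a seeded synthetic-genome generator with ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
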