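Package: retrotome
Title: LTR-Retrotransposon Transcriptome Profiling from Expression Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to profile the transcriptional activity of human endogenous
    retroviruses (HERVs) and mammalian apparent LTR retrotransposons (MaLRs)
    from probeset-level expression microarray data. Provides a coefficient of
    variation calibrated intensity threshold for expression calling, per-sample
    functional assignment of long terminal repeats (promoter, polyadenylation,
    readthrough, silent) from U3/U5 probeset signals, cross-sample
    function-combination profiling, empirical-Bayes moderated t-tests with
    Benjamini-Hochberg correction and tolerisable-phenotype classification over
    an endotoxin-tolerance design, correlation-based integration of
    retrotransposon loci into gene pathways, genomic-context characterisation
    of functional versus silent LTRs, and a synthetic chip-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
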