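Package: mircurate
Title: Discovery, Curation and Annotation of miRNA Hairpins and piRNA
    Clusters from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small RNA-seq annotation toolkit: preprocesses small RNA
    libraries (adapter trimming, size filtering, read collapsing), discovers
    candidate miRNA precursor loci from genome-wide read stacks, validates
    stem-loop secondary structure by base-pair-maximisation folding, applies
    a two-peak Dicer/Drosha read-alignment consistency test to separate high-
    and low-confidence loci, classifies loci by genomic context (UTR, exon,
    intron, intergenic) with a 15 percent overlap rule, detects miRtrons from
    short introns, quantifies non-templated 3' additions (adenylation and
    uridylation) of mature miRNAs, flags arm switching across tissues, and
    calls piRNA clusters with multimapper count reallocation and a 1T/10A
    sequence-signature filter. Includes a synthetic-data generator that
    plants ground-truth hairpins and piRNA clusters in a toy genome for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    methods,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
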