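Package: creLicense
Title: Prioritization of Genes with Developmentally Licensed Stimulus-Responsive Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates stage-labelled RNA-seq counts, 5hmC (CMS-IP) enrichment
    tracks, and ATAC-seq/H3K27Ac peak sets to prioritize genes whose
    stimulus-responsive cis-regulatory elements appear to be licensed by
    active DNA demethylation during T-cell development. Provides strict
    readers for BED/bedGraph/TSV inputs, an interval-overlap engine,
    median-of-ratios count normalization with fold-change gating, gene-body
    5hmC enrichment scoring, developmental CRE detection and stimulus-novel
    peak calling with TSS-distance peak-to-gene assignment, cascade/Venn
    summaries, hypergeometric gene-set enrichment with Benjamini-Hochberg
    correction, and a synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
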