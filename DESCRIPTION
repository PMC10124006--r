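Package: lncdesert
Title: Positional Classification and Expression Characterization of Desert lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies long noncoding RNA (lncRNA) genes by genomic distance to
    protein-coding genes (overlapped, proximal within 50 kb, or desert beyond
    50 kb), normalizes gene-level counts to TPM and FPKM, computes the
    cytoplasm/nucleus relative concentration index (CN.RCI) from fractionated
    RNA-seq, scores stage and cell-type expression specificity with a
    Jensen-Shannon-divergence score and a Normalized Difference contrast,
    applies fold-change and p-value thresholds to differential-expression
    tables, and intersects the resulting calls with the positional classes.
    A seeded synthetic-data generator plants known positional classes,
    stage-specific programs, fold changes and localization ratios so that
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
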