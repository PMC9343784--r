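Package: methslide
Title: Sliding-Window Differential Methylation Analysis for Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of whole-genome bisulfite sequencing (WGBS)
    methylation calls for factorial exposure designs: replicate-pooled Fisher
    exact testing of differentially methylated cytosines (DMCs) with
    Benjamini-Hochberg false discovery control, 1-kb sliding-window calling of
    differentially methylated regions (DMRs) with CpG-count, coverage,
    significance and effect-size criteria plus 200-bp refinement, genomic
    feature classification (promoter/exon/intron/intergenic with a CpG-island
    overlay), cross-contrast Venn/hypergeometric overlap and Pearson
    correlation of methylation differences, z-score clustering matrices,
    GMT-based hypergeometric gene-set enrichment, and scaled meta-gene
    methylation profiles. Includes a beta-binomial methylome simulator that
    emulates a four-group (prenatal x postnatal exposure) design with spiked
    differential regions, so the whole pipeline is testable against known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
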