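#!/usr/bin/env Rscript
# Reproduce the published genomic-distribution table (four contrasts of the
# maternal methamphetamine WGBS study) from its printed per-category counts:
# expand the counts into labelled region rows and let the package recompute
# every count and percentage. Writes results/tables/distribution_<contrast>.tsv.

suppressMessages({
  library(methslide)
  library(data.table)
})
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

counts <- fread(system.file("extdata", "dmr_distribution_counts.tsv",
                            package = "methslide"), sep = "\t")
for (cn in unique(counts$contrast)) {
  s <- summarize_dmr_distribution(
    expand_distribution_counts(counts[contrast == cn]))
  write_tsv(s, file.path("results/tables",
                         paste0("distribution_", cn, ".tsv")))
  cat("\n==", cn, "==\n")
  print(s)
}
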