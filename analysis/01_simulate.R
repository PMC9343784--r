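#!/usr/bin/env Rscript
# Generate the synthetic study fixture: a two-chromosome methylome with the
# four-group factorial design (SAL_SAL, METH_SAL, SAL_METH, METH_METH; three
# replicates each, ~30x coverage) and 20 spiked 30-pp differential regions
# per factor (pre, post, interaction). Writes cytosine reports, annotation,
# truth BED and a pipeline config under results/fixture/.

suppressMessages(library(methslide))

cfg <- sim_config(seed = 1L)
fx <- make_fixture("results/fixture", cfg)

truth <- as.data.frame(fx$truth)
cat("genome:", length(fx$model$chrom_lengths), "chromosomes x",
    cfg$chrom_length, "bp;", nrow(fx$model$genes), "genes;",
    sum(fx$model$sites$context == "CpG"), "CpG sites\n")
cat("truth regions per factor:\n")
print(table(truth$factor_id, truth$direction))
cat("fixture written to results/fixture (config:", fx$config_path, ")\n")
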