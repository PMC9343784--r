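# Shared simulation scenarios, cached so several test files (and the
# acceptance suite) reuse one realisation instead of re-simulating.

.msl_test_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .msl_test_cache)) {
    assign(name, fn(), envir = .msl_test_cache)
  }
  get(name, envir = .msl_test_cache)
}

reps_of <- function(group, n = 3L) paste0(group, "_r", seq_len(n))

# the study-condition factorial scenario: 4 groups x 3 replicates, 30x
# coverage, 30 pp spikes, 20 regions per factor over 2 x 1 Mb chromosomes
scenario_factorial <- function() {
  cached("factorial", function() {
    cfg <- sim_config(seed = 101L)
    model <- build_genome_model(cfg)
    truth <- spike_differential_regions(model, cfg)
    counts <- simulate_counts(model, truth, cfg)
    dmc_pre <- call_dmcs(counts, contrast(
      "SAL_SAL-vs-METH_SAL", reps_of("SAL_SAL"), reps_of("METH_SAL")))
    dmc_post <- call_dmcs(counts, contrast(
      "SAL_SAL-vs-SAL_METH", reps_of("SAL_SAL"), reps_of("SAL_METH")))
    list(cfg = cfg, model = model, truth = truth, counts = counts,
         dmc_pre = dmc_pre, dmc_post = dmc_post)
  })
}

# all-null binomial scenario (no spikes, no overdispersion): the setting in
# which the nominal type-I level of the pooled Fisher test is defined
scenario_null <- function() {
  cached("null", function() {
    cfg <- sim_config(seed = 103L, n_chroms = 1L, n_spiked = 0L,
                      dispersion = 0)
    model <- build_genome_model(cfg)
    truth <- spike_differential_regions(model, cfg)
    counts <- simulate_counts(model, truth, cfg)
    dmc <- call_dmcs(counts, contrast(
      "SAL_SAL-vs-METH_SAL", reps_of("SAL_SAL"), reps_of("METH_SAL")))
    list(cfg = cfg, model = model, counts = counts, dmc = dmc)
  })
}

# shared-direction scenario: "exposure" spikes shift every METH-exposed
# group together, so the prenatal and postnatal contrasts see the same
# effects with the same sign
scenario_shared <- function() {
  cached("shared", function() {
    cfg <- sim_config(seed = 105L)
    model <- build_genome_model(cfg)
    truth <- spike_differential_regions(model, cfg, factors = "exposure")
    counts <- simulate_counts(model, truth, cfg)
    dmc_A <- call_dmcs(counts, contrast(
      "SAL_SAL-vs-METH_SAL", reps_of("SAL_SAL"), reps_of("METH_SAL")))
    dmc_B <- call_dmcs(counts, contrast(
      "SAL_SAL-vs-SAL_METH", reps_of("SAL_SAL"), reps_of("SAL_METH")))
    list(cfg = cfg, truth = truth, dmc_A = dmc_A, dmc_B = dmc_B)
  })
}

# interaction-reversed scenario: "reversal" spikes give the postnatal
# contrast a +delta shift that is inverted in the doubly exposed group
scenario_reversed <- function() {
  cached("reversed", function() {
    cfg <- sim_config(seed = 107L)
    model <- build_genome_model(cfg)
    truth <- spike_differential_regions(model, cfg, factors = "reversal")
    counts <- simulate_counts(model, truth, cfg)
    dmc_A <- call_dmcs(counts, contrast(
      "SAL_SAL-vs-SAL_METH", reps_of("SAL_SAL"), reps_of("SAL_METH")))
    dmc_B <- call_dmcs(counts, contrast(
      "SAL_METH-vs-METH_METH", reps_of("SAL_METH"), reps_of("METH_METH")))
    list(cfg = cfg, truth = truth, dmc_A = dmc_A, dmc_B = dmc_B)
  })
}

# a small annotation set used by classification and metagene tests
tiny_annotation <- function() {
  genes <- data.table::data.table(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
    start = c(10000L, 40000L), end = c(16000L, 52000L),
    strand = c("+", "-"))
  exons <- data.table::data.table(
    gene_id = c("gA", "gA", "gB", "gB"), chrom = "chr1",
    start = c(10000L, 14000L, 40000L, 50000L),
    end = c(11000L, 16000L, 42000L, 52000L))
  islands <- data.table::data.table(chrom = "chr1", start = 30000L,
                                    end = 31000L)
  annotation_set(genes, exons, islands, c(chr1 = 100000L))
}
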