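test_that("generator is deterministic and respects config invariants", {
  cfg <- sim_config(seed = 17L, n_chroms = 2L, chrom_length = 200000L,
                    n_genes = 10L, n_spiked = 4L)
  m1 <- build_genome_model(cfg)
  m2 <- build_genome_model(cfg)
  expect_identical(m1$sites, m2$sites)
  expect_identical(m1$genes, m2$genes)
  expect_identical(m1$islands, m2$islands)
  t1 <- spike_differential_regions(m1, cfg)
  t2 <- spike_differential_regions(m2, cfg)
  expect_identical(as.data.table(t1), as.data.table(t2))
  c1 <- simulate_counts(m1, t1, cfg)
  c2 <- simulate_counts(m2, t2, cfg)
  expect_identical(c1, c2)

  # genes: non-overlapping, within chromosome bounds
  for (ch in unique(m1$genes$chrom)) {
    g <- m1$genes[chrom == ch][order(start)]
    expect_true(all(g$start >= 0 & g$end <= m1$chrom_lengths[[ch]]))
    if (nrow(g) > 1L) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # exons within their gene
  ex <- merge(m1$exons, m1$genes, by = c("gene_id", "chrom"),
              suffixes = c("", ".g"))
  expect_true(all(ex$start >= ex$start.g & ex$end <= ex$end.g))
  # CpG positions strictly increasing per chromosome
  cpg <- m1$sites[context == "CpG"]
  expect_true(all(cpg[, diff(start) > 0, by = chrom]$V1))
})

test_that("island CpG density and fraction behave as configured", {
  cfg <- sim_config(seed = 19L, n_chroms = 1L, chrom_length = 500000L,
                    n_genes = 10L)
  m <- build_genome_model(cfg)
  cpg <- m$sites[context == "CpG"]
  isl_bp <- sum(m$islands$end - m$islands$start)
  bg_bp <- m$chrom_lengths[[1]] - isl_bp
  dens_in <- sum(cpg$island) / isl_bp
  dens_out <- sum(!cpg$island) / bg_bp
  expect_gte(dens_in / dens_out, 5)
  expect_equal(mean(cpg$island), cfg$island_fraction, tolerance = 0.25)
  # CpG context dominates the cytosine map
  expect_gt(mean(m$sites$context == "CpG"), 0.5)

  cfg0 <- sim_config(seed = 19L, n_chroms = 1L, chrom_length = 200000L,
                     n_genes = 5L, island_fraction = 0)
  m0 <- build_genome_model(cfg0)
  expect_identical(sum(m0$sites$island), 0L)
  expect_identical(nrow(m0$islands), 0L)
})

test_that("infeasible gene configurations are rejected", {
  cfg <- sim_config(seed = 1L, n_chroms = 1L, chrom_length = 20000L,
                    n_genes = 50L)
  expect_error(build_genome_model(cfg), "cannot fit")
  expect_error(sim_config(baseline_background = 0.9, delta_pp = 30),
               "outside")
  expect_error(sim_config(dispersion = 1), "dispersion")
})

test_that("spiked truth regions are disjoint, typed and CpG-sufficient", {
  sc <- scenario_factorial()
  truth <- as.data.table(sc$truth)
  expect_identical(nrow(truth), 60L)
  expect_setequal(unique(truth$factor_id), c("pre", "post", "interaction"))
  # per-factor direction balance
  bal <- truth[, mean(direction == "hyper"), by = factor_id]$V1
  expect_true(all(abs(bal - 0.5) <= 0.1))
  # pairwise disjoint
  setorder(truth, chrom, start)
  same <- truth[, if (.N > 1L) .(gap = start[-1] - end[-.N]), by = chrom]
  expect_true(all(same$gap >= 0))
  # each region contains >= 3 CpGs
  cpg <- sc$model$sites[context == "CpG"]
  n_in <- vapply(seq_len(nrow(truth)), function(i) {
    nrow(cpg[chrom == truth$chrom[i] & start >= truth$start[i] &
               start < truth$end[i]])
  }, integer(1))
  expect_true(all(n_in >= 3L))

  cfg0 <- sim_config(seed = 3L, n_spiked = 0L)
  m0 <- build_genome_model(cfg0)
  expect_identical(nrow(spike_differential_regions(m0, cfg0)), 0L)
})

test_that("counts conserve coverage and realise spiked effects", {
  sc <- scenario_factorial()
  counts <- sc$counts
  expect_length(counts, 12L)
  one <- counts[["METH_METH_r2"]]
  expect_true(all(one$count_m >= 0 & one$count_u >= 0))

  pool <- function(group) pool_group_counts(counts, reps_of(group))
  p_ss <- pool("SAL_SAL"); p_ms <- pool("METH_SAL")
  # inside a pre-factor hyper region the METH_SAL pooled mean exceeds the
  # SAL_SAL pooled mean by ~ delta_pp (within 3 binomial SEs)
  truth <- as.data.table(sc$truth)
  hits <- truth[factor_id == "pre" & direction == "hyper"]
  r <- hits[1]
  in_reg <- function(p) p[chrom == r$chrom & start >= r$start &
                            start < r$end & context == "CpG"]
  a <- in_reg(p_ss); b <- in_reg(p_ms)
  m_a <- sum(a$count_m) / sum(a$count_m + a$count_u)
  m_b <- sum(b$count_m) / sum(b$count_m + b$count_u)
  se <- sqrt(m_a * (1 - m_a) / sum(a$count_m + a$count_u) +
               m_b * (1 - m_b) / sum(b$count_m + b$count_u))
  # allow for the replicate-level beta variance on top of binomial SE
  se_tot <- sqrt(se^2 + 2 * sc$cfg$dispersion * 0.25 / (3 * nrow(a)))
  expect_lt(abs((m_b - m_a) - r$delta_pp / 100), 3 * se_tot + 0.02)
})

test_that("delta 0 gives matched group means and dispersion 0 is binomial", {
  sc <- scenario_null()
  counts <- sc$counts
  pool <- function(group) {
    p <- pool_group_counts(counts, reps_of(group))[context == "CpG"]
    sum(p$count_m) / sum(p$count_m + p$count_u)
  }
  expect_lt(abs(pool("SAL_SAL") - pool("METH_SAL")), 0.02)

  # moment check: with dispersion 0, E[(X - cov*m)^2] ~ m(1-m)*cov
  one <- counts[["SAL_SAL_r1"]]
  cpg <- one[context == "CpG" & !rep(FALSE, .N)]
  bg <- sc$model$sites[context == "CpG" & island == FALSE]$start
  sub <- cpg[start %in% bg]
  m0 <- sc$cfg$baseline_background
  cov <- sub$count_m + sub$count_u
  resid2 <- (sub$count_m - cov * m0)^2
  expect_equal(mean(resid2), m0 * (1 - m0) * mean(cov), tolerance = 0.05)
})
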