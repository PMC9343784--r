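test_that("sliding windows tile the chromosome as specified", {
  w <- sliding_windows(2000L, size = 1000L, step = 200L)
  expect_identical(nrow(w), 6L)
  expect_identical(w$start, seq(0L, 1000L, by = 200L))
  expect_true(all(w$end - w$start == 1000L))
  # chromosome shorter than the window -> single truncated window
  w2 <- sliding_windows(500L, 1000L, 200L)
  expect_identical(w2, data.table::data.table(start = 0L, end = 500L))
  # step == size -> non-overlapping tiling covering the chromosome
  w3 <- sliding_windows(3000L, 1000L, 1000L)
  expect_identical(w3$start, c(0L, 1000L, 2000L))
  # non-aligned end -> one truncated tail window
  w4 <- sliding_windows(2100L, 1000L, 200L)
  expect_identical(tail(w4$end, 1L), 2100L)
  expect_identical(nrow(w4), 7L)
})

test_that("window evaluation applies the four criteria in order", {
  mk_dmc <- function(deltas, qs, start0 = 100L) data.table::data.table(
    chrom = "chr1", start = start0 + 100L * seq_along(deltas) , strand = "+",
    m_A = 0.5, m_B = 0.5 + deltas / 100, delta_pp = deltas,
    cov_A = 50L, cov_B = 50L, p = qs, q = qs)
  win <- list(chrom = "chr1", start = 0L, end = 1000L)

  # two CpGs -> min_cpg
  r <- evaluate_window(win, mk_dmc(c(25, 25), c(0.001, 0.5)))
  expect_false(r$candidate)
  expect_identical(r$reason, "min_cpg")
  # no q < 0.01 CpG -> min_sig_cpg
  r <- evaluate_window(win, mk_dmc(c(25, 25, 22), c(0.5, 0.5, 0.5)))
  expect_identical(r$reason, "min_sig_cpg")
  # qualifying window: direction hyper, mean +24
  r <- evaluate_window(win, mk_dmc(c(25, 25, 22), c(0.001, 0.5, 0.5)))
  expect_true(r$candidate)
  expect_identical(r$direction, "hyper")
  expect_equal(r$mean_delta_pp, 24)
  expect_identical(r$n_sig_cpg, 1L)
  expect_lte(r$p_combined, 1)
  # mean +10 below the 20 pp threshold -> min_delta
  r <- evaluate_window(win, mk_dmc(c(30, 30, -30), c(0.001, 0.001, 0.001)))
  expect_identical(r$reason, "min_delta")
  # significant CpG discordant with the mean -> discordant
  r <- evaluate_window(win, mk_dmc(c(40, 40, -15), c(0.5, 0.5, 0.001)))
  expect_identical(r$reason, "discordant")
})

test_that("DMR calling recovers spikes, keeps directions apart, stays null-clean", {
  sc <- scenario_factorial()
  dmr <- call_dmrs(sc$dmc_pre, sc$model$chrom_lengths)
  truth <- as.data.table(sc$truth)[factor_id == "pre"]
  bench <- dmr_benchmark(dmr, truth)
  expect_gte(bench$sensitivity, 0.9)
  expect_lte(bench$fdp, 0.1)

  # hyper and hypo truth regions never produce a merged mixed region
  expect_true(all(dmr$direction %in% c("hyper", "hypo")))
  for (i in seq_len(nrow(dmr))) {
    same <- dmr[chrom == dmr$chrom[i] & start < dmr$end[i] &
                  end > dmr$start[i]]
    expect_true(all(same$direction == dmr$direction[i]))
  }

  # every called DMR satisfies the four criteria when re-checked
  for (i in seq_len(nrow(dmr))) {
    r <- evaluate_window(dmr[i], sc$dmc_pre)
    expect_true(r$candidate)
    expect_identical(r$direction, dmr$direction[i])
    expect_equal(r$mean_delta_pp, dmr$mean_delta_pp[i])
  }

  # null data: essentially no DMRs (<= 1 per Mb)
  nl <- scenario_null()
  dmr0 <- call_dmrs(nl$dmc, nl$model$chrom_lengths)
  expect_lte(nrow(dmr0), 1L)

  # empty input
  e <- call_dmrs(sc$dmc_pre[0], sc$model$chrom_lengths)
  expect_identical(nrow(e), 0L)
})

test_that("spike recovery is monotone in effect size", {
  recover_rate <- function(delta) {
    hits <- 0L; total <- 0L
    for (rep_i in 1:10) {
      cfg <- sim_config(seed = 300L + rep_i, n_chroms = 1L,
                        chrom_length = 200000L, n_genes = 6L,
                        n_spiked = 4L, delta_pp = delta)
      model <- build_genome_model(cfg)
      truth <- spike_differential_regions(model, cfg, factors = "pre")
      counts <- simulate_counts(model, truth, cfg)
      dmc <- call_dmcs(counts, contrast("c", reps_of("SAL_SAL"),
                                        reps_of("METH_SAL")))
      dmr <- call_dmrs(dmc, model$chrom_lengths)
      b <- dmr_benchmark(dmr, truth)
      hits <- hits + b$sensitivity * b$n_truth
      total <- total + b$n_truth
    }
    hits / total
  }
  r <- vapply(c(5, 20, 35), recover_rate, numeric(1))
  expect_gt(r[3], r[1])
  expect_gte(r[2] + 0.05, r[1])
  expect_gte(r[3] + 0.05, r[2])
  expect_lte(r[1], 0.2)
  expect_gte(r[3], 0.9)
})

test_that("refinement returns disjoint in-span 200-bp tiles", {
  dmc <- data.table::data.table(
    chrom = "chr1", start = c(150L, 250L, 450L, 890L), strand = "+",
    m_A = 0.4, m_B = 0.7, delta_pp = 30,
    cov_A = 50L, cov_B = 50L, p = c(1e-5, 1e-4, 0.5, 1e-6),
    q = c(1e-4, 1e-3, 0.8, 1e-5))
  dmr <- list(chrom = "chr1", start = 100L, end = 950L)
  tiles <- refine_subregions(dmr, dmc)
  # significant CpGs at 150, 250, 890; the 0.5-q CpG does not retain a tile
  expect_identical(tiles$start, c(100L, 200L, 800L))
  expect_identical(tiles$end, c(200L, 400L, 950L))
  expect_true(all(tiles$start >= dmr$start & tiles$end <= dmr$end))
  expect_true(all(tiles$n_sig_cpg >= 1L))
  expect_false(attr(tiles, "flagged"))

  # no significant CpG -> empty, flagged
  t0 <- refine_subregions(dmr, dmc[q > 0.5])
  expect_identical(nrow(t0), 0L)
  expect_true(attr(t0, "flagged"))

  # all significant CpGs in one tile -> one tile
  t1 <- refine_subregions(list(chrom = "chr1", start = 200L, end = 400L), dmc)
  expect_identical(nrow(t1), 1L)
})
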