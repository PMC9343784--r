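test_that("set overlap counts and hypergeometric p match enumeration", {
  a <- paste0("chr1:", 1:10, ":+")
  b <- paste0("chr1:", 6:15, ":+")
  ov <- dmc_set_overlap(a, b, universe = 100L)
  expect_identical(ov$n_common, 5L)
  expect_identical(ov$n_A_only, 5L)
  expect_identical(ov$n_B_only, 5L)
  # Venn conservation
  expect_identical(ov$n_A_only + ov$n_common, 10L)
  expect_equal(ov$p_overlap, oracle_hyper_upper(5, 10, 10, 100),
               tolerance = 1e-12)

  # disjoint small sets in a large universe -> p ~ 1
  ov0 <- dmc_set_overlap(a, paste0("chr2:", 1:10, ":+"), universe = 10000L)
  expect_identical(ov0$n_common, 0L)
  expect_equal(ov0$p_overlap, 1)
  # identical sets -> minimal p
  ov1 <- dmc_set_overlap(a, a, universe = 100L)
  expect_identical(ov1$n_common, 10L)
  expect_equal(ov1$p_overlap, oracle_hyper_upper(10, 10, 10, 100),
               tolerance = 1e-12)
  expect_error(dmc_set_overlap(a, b, universe = 5L), "universe")

  # property over random configurations, N <= 200
  set.seed(9)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    ka <- sample(1:(N / 2), 1); kb <- sample(1:(N / 2), 1)
    ua <- paste0("s", sample(N, ka))
    ub <- paste0("s", sample(N, kb))
    ov <- dmc_set_overlap(ua, ub, universe = N)
    expect_equal(ov$p_overlap,
                 oracle_hyper_upper(ov$n_common, ka, kb, N),
                 tolerance = 1e-9)
  }
})

test_that("delta correlations recover trivial and structured signs", {
  mk <- function(deltas, sig) data.table::data.table(
    chrom = "chr1", start = 100L * seq_along(deltas), strand = "+",
    delta_pp = deltas, sig = sig)
  x <- c(-30, -10, 5, 20, 40)
  r1 <- correlate_deltas(mk(x, TRUE), mk(x, TRUE), "union")
  expect_equal(r1$r, 1)
  r2 <- correlate_deltas(mk(x, TRUE), mk(-x, TRUE), "union")
  expect_equal(r2$r, -1)
  # n < 3 -> p missing
  r3 <- correlate_deltas(mk(x[1:2], TRUE), mk(x[1:2], TRUE), "union")
  expect_true(is.na(r3$p))
  # p agrees with cor.test's t transform
  set.seed(2)
  y <- x + rnorm(5, sd = 10)
  r4 <- correlate_deltas(mk(x, TRUE), mk(y, TRUE), "union")
  ref <- stats::cor.test(x, y)
  expect_equal(r4$r, unname(ref$estimate))
  expect_equal(r4$p, ref$p.value, tolerance = 1e-9)

  # shared-direction spikes across contrasts -> strong positive r;
  # interaction-reversed spikes -> strong negative r
  sh <- scenario_shared()
  expect_gt(correlate_deltas(sh$dmc_A, sh$dmc_B, "union")$r, 0.5)
  expect_gt(correlate_deltas(sh$dmc_A, sh$dmc_B, "common")$r, 0.9)
  rv <- scenario_reversed()
  expect_lt(correlate_deltas(rv$dmc_A, rv$dmc_B, "union")$r, -0.5)
  expect_lt(correlate_deltas(rv$dmc_A, rv$dmc_B, "common")$r, -0.9)
})

test_that("z-scoring standardises rows and drops constants", {
  m <- rbind(c(0.2, 0.4, 0.6), c(0.5, 0.5, 0.5), c(1, 0, 1))
  rownames(m) <- c("s1", "s2", "s3")
  expect_warning(z <- zscore_matrix(m), "constant")
  expect_identical(nrow(z), 2L)
  expect_equal(unname(z["s1", ]), c(-1, 0, 1) / sd(c(-1, 0, 1) * 0.2) * 0.2)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 1, sd)), c(1, 1))
})

test_that("hierarchical clustering matches the O(n^3) oracle", {
  # identical columns merge first at height 0
  m <- cbind(a = c(0, 1), b = c(0, 1), c = c(5, 9))
  hc <- hclust_order(m)
  expect_equal(hc$height[1], 0)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))
  # 3 points on a line: the close pair merges first
  m2 <- cbind(x = 0, y = 1, z = 10)
  hc2 <- hclust_order(rbind(m2))
  expect_setequal(abs(hc2$merge[1, ]), c(1, 2))

  set.seed(33)
  for (i in 1:10) {
    mm <- matrix(rnorm(5 * sample(4:8, 1)), nrow = 5)
    colnames(mm) <- paste0("c", seq_len(ncol(mm)))
    got <- hclust_order(mm)$height
    want <- oracle_hclust_complete(mm)
    expect_equal(sort(got), sort(want), tolerance = 1e-9)
  }
})

test_that("gene-set enrichment matches enumeration and handles edge cases", {
  universe <- paste0("g", 1:50)
  sets <- list(hit = paste0("g", 1:10), miss = paste0("g", 41:45))
  query <- paste0("g", c(1:6, 20:23))
  enr <- enrich_gene_sets(query, sets, universe)
  # N=50, K=10, n=10, k=6 against brute-force pmf summation
  expect_equal(enr[set == "hit"]$p, oracle_hyper_upper(6, 10, 10, 50),
               tolerance = 1e-12)
  expect_identical(enr$set[1], "hit")
  expect_equal(enr[set == "miss"]$k, 0L)
  expect_equal(enr[set == "miss"]$p, 1)
  # query = full set = universe -> k=K=n=N -> p = 1
  e2 <- enrich_gene_sets(universe, list(all = universe), universe)
  expect_equal(e2$p, 1)
  expect_error(enrich_gene_sets(c("zz"), sets, universe), "subset")
  expect_error(enrich_gene_sets("g1", sets, character(0)), "empty universe")
})

test_that("methylation matrix builds levels with the chosen fill policy", {
  counts <- list(
    s1 = data.table::data.table(chrom = "chr1", start = c(0L, 10L),
                                strand = "+", context = "CpG",
                                count_m = c(5L, 0L), count_u = c(5L, 0L)),
    s2 = data.table::data.table(chrom = "chr1", start = 0L, strand = "+",
                                context = "CpG", count_m = 9L, count_u = 1L))
  keys <- c("chr1:0:+", "chr1:10:+")
  m <- methylation_matrix(counts, keys)
  expect_equal(m["chr1:0:+", ], c(s1 = 0.5, s2 = 0.9))
  expect_true(all(is.na(m["chr1:10:+", ])))
  m0 <- methylation_matrix(counts, keys, fill = "zero")
  expect_equal(unname(m0["chr1:10:+", ]), c(0, 0))
})
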