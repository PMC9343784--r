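test_that("classification follows precedence, midpoint rule and island overlay", {
  ann <- tiny_annotation()
  # gA: [10000,16000) + strand; promoter [8000,10200); exons [10000,11000)
  # and [14000,16000); island [30000,31000)
  regions <- data.table::data.table(
    chrom = "chr1",
    start = c(9500L, 10050L, 12000L, 15000L, 70000L, 29900L, 30990L),
    end   = c(10500L, 10150L, 13000L, 15500L, 71000L, 30050L, 31500L))
  cls <- classify_region(regions, ann)
  # midpoint 10000 is in both promoter and exon -> Promoter wins
  expect_identical(cls$primary[1], "Promoter")
  expect_identical(cls$primary[2], "Promoter")  # 10100 still within TSS+200
  expect_identical(cls$primary[3], "Introns")
  expect_identical(cls$primary[4], "Exons")
  expect_identical(cls$primary[5], "Intergenic")
  expect_false(cls$cpg_island[5])
  # 1-bp island overlap flips the flag regardless of the primary label
  expect_true(cls$cpg_island[6])
  expect_true(cls$cpg_island[7])

  # minus-strand promoter of gB ([40000,52000), -): [51800, 54000)
  p <- classify_region(data.table::data.table(chrom = "chr1", start = 52500L,
                                              end = 52600L), ann)
  expect_identical(p$primary, "Promoter")

  # any-overlap rule: a region touching an exon anywhere is exonic
  a <- classify_region(data.table::data.table(chrom = "chr1", start = 13800L,
                                              end = 14100L), ann,
                       rule = "any")
  expect_identical(a$primary, "Exons")

  expect_error(classify_region(
    data.table::data.table(chrom = "chrZ", start = 0L, end = 10L), ann),
    "outside")
})

test_that("distribution summary reproduces counts and percentages", {
  # partition property on a synthetic labelled set, against a hand recount
  set.seed(11)
  n <- 500L
  dmrs <- data.table::data.table(
    direction = sample(c("hyper", "hypo"), n, replace = TRUE),
    primary = sample(c("Exons", "Intergenic", "Introns", "Promoter"), n,
                     replace = TRUE, prob = c(0.1, 0.5, 0.35, 0.05)),
    cpg_island = runif(n) < 0.05)
  s <- summarize_dmr_distribution(dmrs)
  expect_identical(s[category == "DMR"]$n, n)
  prim <- s[!category %in% c("DMR", "CpG islands")]
  expect_identical(sum(prim$n), n)
  expect_identical(s$n_hyper + s$n_hypo, s$n)
  for (cc in prim$category) {
    sub <- dmrs[primary == cc]
    expect_identical(prim[category == cc]$n, nrow(sub))
    expect_equal(prim[category == cc]$pct_hyper,
                 round(100 * mean(sub$direction == "hyper"), 4))
  }
  expect_identical(s[category == "CpG islands"]$n, sum(dmrs$cpg_island))
  # hyper + hypo percentages sum to 100 per non-empty row
  nonzero <- s[n > 0]
  expect_true(all(abs(nonzero$pct_hyper + nonzero$pct_hypo - 100) < 0.001))

  # zero-count category reports zeros
  s0 <- summarize_dmr_distribution(dmrs[primary != "Promoter"])
  expect_identical(s0[category == "Promoter"]$n, 0L)
  expect_identical(s0[category == "Promoter"]$pct_hyper, 0)
})

test_that("expanded reference counts round-trip through the summary", {
  counts <- data.table::data.table(
    category = c("Exons", "Intergenic", "Introns", "Promoter", "CpG islands"),
    n_hyper = c(3L, 10L, 5L, 2L, 4L),
    n_hypo = c(1L, 6L, 3L, 0L, 1L))
  rows <- expand_distribution_counts(counts)
  expect_identical(nrow(rows), 30L)
  s <- summarize_dmr_distribution(rows)
  expect_identical(s[category == "Intergenic"]$n_hyper, 10L)
  expect_identical(s[category == "CpG islands"]$n_hyper, 4L)
  expect_identical(s[category == "DMR"]$n, 30L)
})

test_that("gene assignment prefers overlap, then nearest TSS with tie rules", {
  ann <- tiny_annotation()
  # inside gA's intron -> gA
  r <- assign_gene(data.table::data.table(chrom = "chr1", start = 12000L,
                                          end = 12100L), ann)
  expect_identical(r$gene_id, "gA")
  expect_identical(r$distance, 0L)
  # 5 kb upstream of gA's TSS (10000): region at 5000 -> gA
  r <- assign_gene(data.table::data.table(chrom = "chr1", start = 4900L,
                                          end = 5000L), ann)
  expect_identical(r$gene_id, "gA")
  expect_gt(r$distance, 0L)
  # beyond max_distance -> unassigned
  r <- assign_gene(data.table::data.table(chrom = "chr1", start = 80000L,
                                          end = 80100L), ann)
  expect_true(is.na(r$gene_id))

  # equidistant genes -> lexicographically first, flagged
  genes <- data.table::data.table(
    gene_id = c("gB", "gA"), chrom = "chr1",
    start = c(20000L, 0L), end = c(30000L, 5000L), strand = c("+", "-"))
  exons <- data.table::data.table(
    gene_id = c("gB", "gA"), chrom = "chr1",
    start = c(20000L, 0L), end = c(30000L, 5000L))
  ann2 <- annotation_set(genes, exons,
                         data.table::data.table(chrom = character(0),
                                                start = integer(0),
                                                end = integer(0)),
                         c(chr1 = 50000L))
  # TSSs at 20000 (gB, +) and 4999 (gA, -); midpoint region equidistant
  r <- assign_gene(data.table::data.table(chrom = "chr1", start = 12499L,
                                          end = 12501L), ann2)
  expect_identical(r$gene_id, "gA")
  expect_true(r$tie)
})
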