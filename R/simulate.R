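#' Simulation configuration for a four-group synthetic methylome
#'
#' Defines the study conditions emulated by the generator: a four-group
#' factorial design (`SAL_SAL`, `METH_SAL`, `SAL_METH`, `METH_METH`;
#' prenatal x postnatal exposure) with `n_replicates` biological replicates
#' per group, CpG-resolution beta-binomial counts, and spiked differential
#' regions of known effect size.
#'
#' @param n_chroms number of chromosomes (all of length `chrom_length`).
#' @param chrom_length chromosome length in bp.
#' @param n_genes total gene count, distributed across chromosomes.
#' @param island_fraction target proportion of CpG-context sites falling
#'   inside CpG islands. Island CpG density is 10x the background density.
#' @param baseline_island,baseline_background mean methylation level (0-1)
#'   of CpG sites inside / outside islands. Defaults mirror the mammalian
#'   pattern of hypomethylated islands in a methylated background, kept far
#'   enough from 0 and 1 that a `delta_pp` shift in either direction stays in
#'   range.
#' @param baseline_noncpg mean methylation of CHG/CHH sites; near zero, as
#'   non-CpG methylation is low in adult brain.
#' @param dispersion beta-binomial overdispersion (correlation parameter,
#'   0 <= rho < 1); 0 gives plain binomial counts.
#' @param mean_coverage mean read depth per cytosine per sample.
#' @param coverage_size negative-binomial size for coverage (moderate
#'   overdispersion typical of WGBS).
#' @param n_replicates replicates per group.
#' @param n_spiked number of spiked truth regions per factor.
#' @param delta_pp spiked effect size in percentage points.
#' @param dropout per-site per-sample probability of a missing record.
#' @param cpg_rate_background,cpg_rate_island per-bp CpG site rates outside /
#'   inside islands.
#' @param chg_rate,chh_rate per-bp rates of non-CpG cytosine sites (kept low
#'   so CpG-context sites dominate the cytosine map).
#' @param seed integer seed; all generator operations are deterministic
#'   given the seed.
#'
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 1e6, n_genes = 60L,
                       island_fraction = 0.15,
                       baseline_island = 0.30, baseline_background = 0.60,
                       baseline_noncpg = 0.005,
                       dispersion = 0.05, mean_coverage = 30,
                       coverage_size = 10, n_replicates = 3L,
                       n_spiked = 20L, delta_pp = 30, dropout = 0,
                       cpg_rate_background = 0.01, cpg_rate_island = 0.10,
                       chg_rate = 0.002, chh_rate = 0.004, seed = 1L) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes), island_fraction = island_fraction,
    baseline_island = baseline_island,
    baseline_background = baseline_background,
    baseline_noncpg = baseline_noncpg, dispersion = dispersion,
    mean_coverage = mean_coverage, coverage_size = coverage_size,
    n_replicates = as.integer(n_replicates), n_spiked = as.integer(n_spiked),
    delta_pp = delta_pp, dropout = dropout,
    cpg_rate_background = cpg_rate_background,
    cpg_rate_island = cpg_rate_island,
    chg_rate = chg_rate, chh_rate = chh_rate, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_chroms >= 1L, cfg$chrom_length > 0L, cfg$n_genes >= 0L,
    cfg$island_fraction >= 0, cfg$island_fraction < 1,
    cfg$dispersion >= 0, cfg$dispersion < 1,
    cfg$mean_coverage > 0, cfg$n_replicates >= 1L, cfg$n_spiked >= 0L,
    cfg$delta_pp >= 0, cfg$dropout >= 0, cfg$dropout < 1,
    cfg$cpg_rate_island >= 5 * cfg$cpg_rate_background
  )
  for (b in c(cfg$baseline_island, cfg$baseline_background,
              cfg$baseline_noncpg)) {
    if (b < 0 || b > 1) stop("baseline methylation levels must lie in [0, 1]")
  }
  # spikes are placed on background (non-island) CpGs: a shift of delta_pp in
  # either direction must keep the group mean inside [0, 1]
  d <- cfg$delta_pp / 100
  if (cfg$baseline_background + d > 1 || cfg$baseline_background - d < 0) {
    stop("delta_pp would push background group means outside [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chroms, "chrom x", x$chrom_length, "bp,",
      x$n_genes, "genes,", 4L * x$n_replicates, "samples, delta",
      x$delta_pp, "pp, seed", x$seed, "\n")
  invisible(x)
}

# group labels of the factorial design, fixed order
.msl_groups <- function() c("SAL_SAL", "METH_SAL", "SAL_METH", "METH_METH")

# factor -> signed group shift multipliers. pre/post/interaction are the
# factorial factors; exposure (any-METH shift) and reversal (postnatal
# response abolished and inverted by prenatal exposure) generate the
# shared-direction and sign-flipped cross-contrast structures.
.msl_factor_shifts <- function() {
  list(
    pre         = c(METH_SAL = 1, METH_METH = 1),
    post        = c(SAL_METH = 1, METH_METH = 1),
    interaction = c(METH_METH = 1),
    exposure    = c(METH_SAL = 1, SAL_METH = 1, METH_METH = 1),
    reversal    = c(SAL_METH = 1, METH_METH = -1)
  )
}

# positions (1-based) in (0, L] with per-bp rate via geometric gaps
.sim_positions <- function(L, rate) {
  if (rate <= 0 || L < 1) return(integer(0))
  out <- integer(0)
  last <- 0L
  while (last < L) {
    n_draw <- max(50L, ceiling((L - last) * rate * 1.3))
    gaps <- stats::rgeom(n_draw, prob = rate) + 1L
    pos <- last + cumsum(gaps)
    out <- c(out, pos[pos <= L])
    last <- if (length(pos)) max(pos) else L
  }
  out
}

# place n non-overlapping intervals of given lengths on [0, L) by slotting
.sim_place_intervals <- function(L, lens, what = "interval") {
  n <- length(lens)
  if (n == 0L) return(data.table(start = integer(0), end = integer(0)))
  slot <- floor(L / n)
  if (any(lens + 2L > slot)) {
    stop("cannot fit ", n, " non-overlapping ", what, "s of length up to ",
         max(lens), " on a ", L, " bp chromosome")
  }
  offset <- vapply(seq_len(n), function(i) {
    sample.int(slot - lens[i] - 1L, 1L)
  }, integer(1))
  start <- (seq_len(n) - 1L) * slot + offset
  data.table(start = as.integer(start), end = as.integer(start + lens))
}

#' Build a synthetic genome model
#'
#' Generates chromosome lengths, non-overlapping gene models with exon
#' structure, CpG islands, and a cytosine site map (CpG/CHG/CHH contexts)
#' with island CpG density at least 5x the background density.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `genome_model`: list with `chrom_lengths` (named
#'   integer), `genes`, `exons`, `islands`, `sites` (data.tables, 0-based
#'   half-open coordinates), and the `config`.
#' @export
build_genome_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_lengths <- setNames(rep(config$chrom_length, config$n_chroms), chroms)

  # genes per chromosome, round-robin
  n_per <- diff(floor(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  genes_l <- list(); exons_l <- list(); islands_l <- list(); sites_l <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    L <- config$chrom_length
    n_g <- n_per[ci]
    glens <- integer(0)
    if (n_g > 0L) {
      max_len <- min(15000L, floor(L / n_g) - 200L)
      if (max_len < 1000L) {
        stop("cannot fit ", n_g, " non-overlapping genes on a ", L,
             " bp chromosome")
      }
      min_len <- max(1000L, min(5000L, floor(max_len / 2)))
      glens <- as.integer(round(runif(n_g, min_len, max_len)))
    }
    gpos <- .sim_place_intervals(L, glens, what = "gene")
    if (n_g > 0L) {
      gpos[, `:=`(
        gene_id = sprintf("g%04d", gid + seq_len(n_g)),
        chrom = chroms[ci],
        strand = sample(c("+", "-"), n_g, replace = TRUE)
      )]
      gid <- gid + n_g
      # exon/intron structure: 2-6 exons, first and last flush with the gene
      ex <- lapply(seq_len(n_g), function(i) {
        len <- glens[i]
        k <- sample(2:6, 1L)
        bounds <- sort(sample(seq(50L, len - 50L), 2L * (k - 1L)))
        seg <- c(0L, bounds, len)
        s <- seg[seq(1L, length(seg) - 1L, by = 2L)]
        e <- seg[seq(2L, length(seg), by = 2L)]
        data.table(gene_id = gpos$gene_id[i], chrom = chroms[ci],
                   start = gpos$start[i] + s, end = gpos$start[i] + e)
      })
      exons_l[[ci]] <- rbindlist(ex)
      genes_l[[ci]] <- gpos[, .(gene_id, chrom, start, end, strand)]
    }

    # islands sized so that the expected island share of CpGs hits the target
    f <- config$island_fraction
    rb <- config$cpg_rate_background; ri <- config$cpg_rate_island
    if (f > 0) {
      Bi <- f * rb * L / (ri * (1 - f) + f * rb)
      ilens <- as.integer(round(runif(max(1L, round(Bi / 1000)), 600, 1400)))
      isl <- .sim_place_intervals(L, ilens, what = "island")
      isl[, chrom := chroms[ci]]
    } else {
      isl <- data.table(start = integer(0), end = integer(0),
                        chrom = character(0))
    }
    islands_l[[ci]] <- isl[, .(chrom, start, end)]

    # cytosine map: background CpG everywhere, dense CpG inside islands,
    # sparse CHG/CHH background
    pos_bg <- .sim_positions(L, rb)
    pos_isl <- integer(0)
    if (nrow(isl)) {
      for (r in seq_len(nrow(isl))) {
        w <- isl$end[r] - isl$start[r]
        pos_isl <- c(pos_isl, isl$start[r] + .sim_positions(w, ri))
      }
      in_isl <- rep(FALSE, length(pos_bg))
      for (r in seq_len(nrow(isl))) {
        in_isl <- in_isl | (pos_bg > isl$start[r] & pos_bg <= isl$end[r])
      }
      pos_bg <- pos_bg[!in_isl]
    }
    pos_cpg <- sort(unique(c(pos_bg, pos_isl)))
    pos_chg <- .sim_positions(L, config$chg_rate)
    pos_chh <- .sim_positions(L, config$chh_rate)
    # non-CpG sites colliding with CpG positions are dropped
    pos_chg <- setdiff(pos_chg, pos_cpg)
    pos_chh <- setdiff(pos_chh, c(pos_cpg, pos_chg))
    st <- data.table(
      chrom = chroms[ci],
      start = as.integer(c(pos_cpg, pos_chg, pos_chh) - 1L),
      context = rep(c("CpG", "CHG", "CHH"),
                    c(length(pos_cpg), length(pos_chg), length(pos_chh)))
    )
    st[, strand := sample(c("+", "-"), .N, replace = TRUE)]
    isl_flag <- rep(FALSE, nrow(st))
    if (nrow(isl)) {
      for (r in seq_len(nrow(isl))) {
        isl_flag <- isl_flag | (st$start >= isl$start[r] & st$start < isl$end[r])
      }
    }
    st[, island := isl_flag & context == "CpG"]
    setorder(st, start)
    sites_l[[ci]] <- st
  }

  model <- list(
    chrom_lengths = chrom_lengths,
    genes = if (length(genes_l)) rbindlist(genes_l) else
      data.table(gene_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0)),
    exons = if (length(exons_l)) rbindlist(exons_l) else
      data.table(gene_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0)),
    islands = rbindlist(islands_l),
    sites = rbindlist(sites_l),
    config = config
  )
  setorder(model$sites, chrom, start)
  setorder(model$genes, chrom, start)
  structure(model, class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_lengths), "chromosomes,",
      nrow(x$genes), "genes,", nrow(x$islands), "islands,",
      nrow(x$sites), "cytosine sites (",
      sum(x$sites$context == "CpG"), "CpG )\n")
  invisible(x)
}

#' Spike differential truth regions into a genome model
#'
#' Selects disjoint 1-kb regions with at least three background CpGs (no
#' island CpGs, so a shift in either direction stays within [0, 1]) and
#' assigns each a factor and a direction. Directions are balanced ~50/50
#' within each factor. Regions are separated by at least two window widths so
#' distinct truth regions can never be merged by the region caller.
#'
#' @param model a [build_genome_model()] result.
#' @param config the [sim_config()] used to build the model.
#' @param factors factor labels to spike; each receives `config$n_spiked`
#'   regions. Supported: `pre`, `post`, `interaction` (factorial design),
#'   `exposure` (all METH-exposed groups shift together) and `reversal`
#'   (postnatal shift inverted under prenatal exposure).
#' @param region_size truth region width in bp.
#' @return object of class `truth_set`: data.table with columns
#'   chrom, start, end, factor_id, direction, delta_pp.
#' @export
spike_differential_regions <- function(model, config,
                                       factors = c("pre", "post", "interaction"),
                                       region_size = 1000L) {
  stopifnot(inherits(model, "genome_model"), inherits(config, "sim_config"))
  stopifnot(all(factors %in% names(.msl_factor_shifts())))
  set.seed(config$seed + 1L)
  n_total <- config$n_spiked * length(factors)
  empty <- data.table(chrom = character(0), start = integer(0),
                      end = integer(0), factor_id = character(0),
                      direction = character(0), delta_pp = numeric(0))
  if (n_total == 0L) return(structure(empty, class = c("truth_set", class(empty))))

  # candidate windows: region_size tiles with >=3 non-island CpGs and no
  # island CpGs
  cand <- list()
  cs <- model$sites[context == "CpG"]
  for (ch in names(model$chrom_lengths)) {
    L <- model$chrom_lengths[[ch]]
    starts <- seq(0L, L - region_size, by = region_size)
    s <- cs[chrom == ch]
    tile <- findInterval(s$start, starts)
    n_ok <- tabulate(tile, nbins = length(starts))
    n_isl <- tabulate(tile[s$island], nbins = length(starts))
    keep <- which(n_ok >= 3L & n_isl == 0L)
    if (length(keep)) {
      cand[[ch]] <- data.table(chrom = ch, tile = keep,
                               start = starts[keep],
                               end = starts[keep] + region_size)
    }
  }
  cand <- rbindlist(cand)
  if (nrow(cand) < n_total) {
    stop("insufficient eligible windows: need ", n_total, ", found ", nrow(cand))
  }
  # greedy sample enforcing >= 2 tiles of separation on the same chromosome
  cand <- cand[sample(.N)]
  chosen <- integer(0)
  taken <- list()
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]; tl <- cand$tile[i]
    prev <- taken[[ch]]
    if (is.null(prev) || all(abs(prev - tl) >= 3L)) {
      chosen <- c(chosen, i)
      taken[[ch]] <- c(prev, tl)
      if (length(chosen) == n_total) break
    }
  }
  if (length(chosen) < n_total) {
    stop("insufficient eligible windows after enforcing separation: need ",
         n_total, ", placed ", length(chosen))
  }
  truth <- cand[chosen][, .(chrom, start, end)]
  truth[, factor_id := rep(factors, each = config$n_spiked)]
  truth[, direction := unlist(lapply(factors, function(f) {
    d <- rep(c("hyper", "hypo"), length.out = config$n_spiked)
    sample(d)
  }))]
  truth[, delta_pp := config$delta_pp]
  setorder(truth, chrom, start)
  structure(truth, class = c("truth_set", class(truth)))
}

# beta-binomial draw: size n, mean m, correlation rho (0 -> binomial)
.rbetabinom <- function(n_sites, size, m, rho) {
  if (rho <= 0) return(rbinom(n_sites, size, m))
  a <- m * (1 - rho) / rho
  b <- (1 - m) * (1 - rho) / rho
  pr <- numeric(n_sites)
  pos <- m > 0 & m < 1
  pr[pos] <- rbeta(sum(pos), a[pos], b[pos])
  pr[m >= 1] <- 1
  rbinom(n_sites, size, pr)
}

#' Simulate per-sample cytosine counts
#'
#' Draws per-site coverage (negative binomial, mean `mean_coverage`, size
#' `coverage_size`) and methylated counts (beta-binomial around the group
#' mean) for every sample of the four-group design. Inside truth regions the
#' group mean is shifted by `delta_pp` for the groups the region's factor
#' touches. Deterministic given the config seed; all samples share the site
#' map unless `dropout > 0`.
#'
#' @param model a [build_genome_model()] result.
#' @param truth a [spike_differential_regions()] result (may be empty).
#' @param config the [sim_config()].
#' @return named list of `4 * n_replicates` data.tables (sample ids like
#'   `SAL_SAL_r1`), each with columns chrom, start, strand, context,
#'   count_m, count_u.
#' @export
simulate_counts <- function(model, truth, config) {
  stopifnot(inherits(model, "genome_model"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  groups <- .msl_groups()
  shifts <- .msl_factor_shifts()
  sites <- model$sites
  n <- nrow(sites)

  base <- ifelse(sites$context != "CpG", config$baseline_noncpg,
                 ifelse(sites$island, config$baseline_island,
                        config$baseline_background))
  M <- matrix(base, nrow = n, ncol = length(groups),
              dimnames = list(NULL, groups))
  if (!is.null(truth) && nrow(truth)) {
    for (r in seq_len(nrow(truth))) {
      idx <- which(sites$chrom == truth$chrom[r] &
                     sites$start >= truth$start[r] &
                     sites$start < truth$end[r] &
                     sites$context == "CpG")
      if (!length(idx)) next
      sgn <- if (truth$direction[r] == "hyper") 1 else -1
      mult <- shifts[[truth$factor_id[r]]]
      for (g in names(mult)) {
        M[idx, g] <- pmin(1, pmax(0, M[idx, g] +
                                    sgn * mult[[g]] * truth$delta_pp[r] / 100))
      }
    }
  }

  out <- list()
  for (g in groups) {
    for (rep_i in seq_len(config$n_replicates)) {
      sid <- paste0(g, "_r", rep_i)
      cov <- rnbinom(n, mu = config$mean_coverage, size = config$coverage_size)
      meth <- .rbetabinom(n, cov, M[, g], config$dispersion)
      dt <- data.table(chrom = sites$chrom, start = sites$start,
                       strand = sites$strand, context = sites$context,
                       count_m = as.integer(meth),
                       count_u = as.integer(cov - meth))
      if (config$dropout > 0) {
        dt <- dt[runif(.N) >= config$dropout]
      }
      out[[sid]] <- dt
    }
  }
  out
}
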