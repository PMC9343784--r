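#' Sliding windows over a chromosome
#'
#' Windows of `size` bp start at multiples of `step` and tile
#' `[0, chrom_length)`. When the last full window does not reach the
#' chromosome end, one truncated window is appended; a chromosome shorter
#' than `size` yields a single truncated window.
#'
#' @param chrom_length chromosome length in bp.
#' @param size window size in bp (default 1000).
#' @param step step between window starts (default 200, chosen so window
#'   phase aligns with the 200-bp refinement tiles).
#' @return data.table with start, end (0-based half-open).
#' @export
sliding_windows <- function(chrom_length, size = 1000L, step = 200L) {
  stopifnot(size >= step, step >= 1L, chrom_length > 0L)
  if (chrom_length <= size) {
    return(data.table(start = 0L, end = as.integer(chrom_length)))
  }
  starts <- seq(0L, as.integer(chrom_length) - as.integer(size),
                by = as.integer(step))
  ends <- starts + as.integer(size)
  if (tail(ends, 1L) < chrom_length) {
    starts <- c(starts, tail(starts, 1L) + as.integer(step))
    ends <- c(ends, as.integer(chrom_length))
  }
  data.table(start = starts, end = ends)
}

# signed-Z Stouffer combination of two-sided p-values, weights sqrt(coverage)
.stouffer_p <- function(p, delta, weight) {
  p <- pmax(p, 1e-300)
  z <- ifelse(delta >= 0, 1, -1) * qnorm(p / 2, lower.tail = FALSE)
  Z <- sum(weight * z) / sqrt(sum(weight^2))
  2 * pnorm(abs(Z), lower.tail = FALSE)
}

# evaluate the four region criteria on a set of member CpGs; returns a list
.eval_members <- function(mem, min_cpg, sig_q, min_delta) {
  n <- nrow(mem)
  if (n < min_cpg) return(list(candidate = FALSE, reason = "min_cpg"))
  sig_idx <- mem$q < sig_q
  n_sig <- sum(sig_idx)
  if (n_sig < 1L) return(list(candidate = FALSE, reason = "min_sig_cpg"))
  mean_delta <- mean(mem$delta_pp)
  if (abs(mean_delta) < min_delta) {
    return(list(candidate = FALSE, reason = "min_delta"))
  }
  if (any(sign(mem$delta_pp[sig_idx]) != sign(mean_delta))) {
    return(list(candidate = FALSE, reason = "discordant"))
  }
  p_comb <- .stouffer_p(mem$p, mem$delta_pp, sqrt(mem$cov_A + mem$cov_B))
  list(candidate = TRUE, reason = NA_character_, n_cpg = n,
       mean_delta_pp = mean_delta,
       direction = if (mean_delta > 0) "hyper" else "hypo",
       n_sig_cpg = n_sig, p_combined = p_comb)
}

#' Evaluate one window against the region criteria
#'
#' Criteria, applied in order: (1) at least `min_cpg` tested CpGs; (2) at
#' least one CpG with q below `sig_q`; (3) absolute mean methylation
#' difference of at least `min_delta_pp` percentage points, with the
#' qualifying CpGs' differences concordant in sign with the mean;
#' (4) coverage-weighted Stouffer combined p recorded. The rejection reason
#' is the first failed criterion.
#'
#' @param window list or one-row data.frame with chrom, start, end.
#' @param dmc_table a [call_dmcs()] table (coverage filter already applied).
#' @param min_cpg,sig_q,min_delta_pp criterion parameters.
#' @return list with `candidate` (logical), `reason` (NA for candidates) and,
#'   for candidates, n_cpg, mean_delta_pp, direction, n_sig_cpg, p_combined.
#' @export
evaluate_window <- function(window, dmc_table, min_cpg = 3L, sig_q = 0.01,
                            min_delta_pp = 20) {
  mem <- as.data.table(dmc_table)[
    chrom == window$chrom & start >= window$start & start < window$end]
  res <- .eval_members(mem, min_cpg, sig_q, min_delta_pp)
  c(list(chrom = window$chrom, start = window$start, end = window$end), res)
}

#' Call differentially methylated regions
#'
#' Evaluates every sliding window against the region criteria
#' (see [evaluate_window()]), BH-adjusts the combined p-values across
#' candidate windows genome-wide, keeps windows with `q_region <= alpha`
#' (or raw `p <= alpha` with `multiplicity = "raw"`), and merges
#' overlapping kept windows of the same direction into maximal runs whose
#' statistics are recomputed over the union of member CpGs. Merged regions
#' are re-checked against all four criteria; the rare merged region that no
#' longer satisfies them is dropped and logged.
#'
#' @param dmc_table a [call_dmcs()] table.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param size,step sliding-window geometry (bp).
#' @param alpha region-level significance threshold.
#' @param min_cpg,sig_q,min_delta_pp region criteria (defaults: >= 3 CpGs,
#'   one CpG with q < 0.01, mean difference >= 20 percentage points).
#' @param multiplicity `"fdr"` (BH across candidate windows, default) or
#'   `"raw"` (unadjusted p).
#' @return data.table of class `dmr_table`: chrom, start, end, n_cpg,
#'   mean_delta_pp, direction, n_sig_cpg, p_combined, q_region. Attributes:
#'   `rejections` (reason counts per window), `n_windows`, `contrast`.
#' @export
call_dmrs <- function(dmc_table, chrom_lengths, size = 1000L, step = 200L,
                      alpha = 0.05, min_cpg = 3L, sig_q = 0.01,
                      min_delta_pp = 20, multiplicity = c("fdr", "raw")) {
  multiplicity <- match.arg(multiplicity)
  dmc <- as.data.table(dmc_table)
  empty <- data.table(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpg = integer(0),
                      mean_delta_pp = numeric(0), direction = character(0),
                      n_sig_cpg = integer(0), p_combined = numeric(0),
                      q_region = numeric(0))
  finish <- function(dt, rej, n_win) {
    setattr(dt, "rejections", rej)
    setattr(dt, "n_windows", n_win)
    setattr(dt, "contrast", attr(dmc_table, "contrast"))
    setattr(dt, "class", c("dmr_table", class(dt)))
    dt[]
  }
  if (!nrow(dmc)) return(finish(empty, data.table(), 0L))

  # window membership by interval join, then grouped criteria
  win_l <- lapply(names(chrom_lengths), function(ch) {
    w <- sliding_windows(chrom_lengths[[ch]], size, step)
    w[, chrom := ch]
    w
  })
  wins <- rbindlist(win_l)
  wins[, win := .I]
  dmc_pts <- dmc[, .(chrom, start, end = start + 1L, delta_pp, p, q,
                     cov_A, cov_B)]
  setkey(wins, chrom, start, end)
  ov <- foverlaps(dmc_pts, wins, by.x = c("chrom", "start", "end"),
                  type = "within", nomatch = NULL)
  # ov: start/end = window span, i.start = CpG position
  stats <- ov[, {
    res <- .eval_members(
      data.table(delta_pp = delta_pp, p = p, q = q, cov_A = cov_A,
                 cov_B = cov_B),
      min_cpg, sig_q, min_delta_pp)
    if (res$candidate) {
      .(candidate = TRUE, reason = NA_character_, n_cpg = res$n_cpg,
        mean_delta_pp = res$mean_delta_pp, direction = res$direction,
        n_sig_cpg = res$n_sig_cpg, p_combined = res$p_combined)
    } else {
      .(candidate = FALSE, reason = res$reason, n_cpg = .N,
        mean_delta_pp = NA_real_, direction = NA_character_,
        n_sig_cpg = NA_integer_, p_combined = NA_real_)
    }
  }, by = .(win, chrom, start, end)]
  # windows with zero members fail min_cpg implicitly; count them in the log
  n_empty <- nrow(wins) - nrow(stats)
  rej <- stats[candidate == FALSE, .N, by = reason]
  if (n_empty > 0L) {
    rej <- rbind(rej, data.table(reason = "min_cpg", N = n_empty))
    rej <- rej[, .(N = sum(N)), by = reason]
  }
  cand <- stats[candidate == TRUE]
  if (!nrow(cand)) return(finish(empty, rej, nrow(wins)))

  cand[, q_region := if (multiplicity == "fdr") bh_adjust(p_combined)
       else p_combined]
  kept <- cand[q_region <= alpha]
  if (!nrow(kept)) return(finish(empty, rej, nrow(wins)))

  # merge overlapping same-direction windows into maximal runs
  setorder(kept, chrom, direction, start)
  kept[, grp := cumsum(
    c(1L, as.integer(start[-1] >= cummax(head(end, -1L))))),
    by = .(chrom, direction)]

  # recompute statistics over the union CpG set; when null CpGs between
  # strong windows dilute the union below the criteria, fall back to the
  # strongest member window (which satisfies them by construction)
  out_l <- list()
  trimmed <- 0L
  for (key in unique(kept[, paste(chrom, direction, grp)])) {
    run <- kept[paste(chrom, direction, grp) == key]
    span <- c(min(run$start), max(run$end))
    mem <- dmc[chrom == run$chrom[1] & start >= span[1] & start < span[2]]
    res <- .eval_members(mem, min_cpg, sig_q, min_delta_pp)
    if (!res$candidate || res$direction != run$direction[1]) {
      best <- run[which.min(p_combined)]
      span <- c(best$start, best$end)
      mem <- dmc[chrom == best$chrom & start >= span[1] & start < span[2]]
      res <- .eval_members(mem, min_cpg, sig_q, min_delta_pp)
      trimmed <- trimmed + 1L
    }
    out_l[[key]] <- data.table(
      chrom = run$chrom[1], start = span[1], end = span[2],
      n_cpg = res$n_cpg, mean_delta_pp = res$mean_delta_pp,
      direction = res$direction, n_sig_cpg = res$n_sig_cpg,
      p_combined = res$p_combined, q_region = min(run$q_region))
  }
  out <- rbindlist(out_l)
  if (!nrow(out)) return(finish(empty, rej, nrow(wins)))
  if (trimmed > 0L) {
    rej <- rbind(rej, data.table(reason = "merged_trimmed", N = trimmed))
  }
  setorder(out, chrom, start)
  finish(out, rej, nrow(wins))
}

#' Refine a DMR into significant 200-bp tiles
#'
#' Genome-aligned tiles of `tile` bp overlapping the region are clipped to
#' its span; tiles retaining at least one member CpG with `q <= q_max` are
#' returned. A region with no significant CpG at all (possible after
#' merging) returns an empty tile list and is flagged.
#'
#' @param dmr list or one-row data.frame with chrom, start, end.
#' @param dmc_table a [call_dmcs()] table.
#' @param tile tile width in bp.
#' @param q_max per-CpG significance threshold defining DMC membership.
#' @return data.table chrom, start, end, n_sig_cpg of retained tiles, with
#'   attribute `flagged = TRUE` when no tile is retained.
#' @export
refine_subregions <- function(dmr, dmc_table, tile = 200L, q_max = 0.05) {
  dmc <- as.data.table(dmc_table)
  t0 <- as.integer(floor(dmr$start / tile) * tile)
  tstarts <- seq(t0, dmr$end - 1L, by = tile)
  tiles <- data.table(chrom = dmr$chrom,
                      start = pmax(tstarts, as.integer(dmr$start)),
                      end = pmin(tstarts + as.integer(tile),
                                 as.integer(dmr$end)))
  sig <- dmc[chrom == dmr$chrom & q <= q_max &
               start >= dmr$start & start < dmr$end]
  tiles[, n_sig_cpg := vapply(seq_len(.N), function(i) {
    sum(sig$start >= tiles$start[i] & sig$start < tiles$end[i])
  }, integer(1))]
  out <- tiles[n_sig_cpg >= 1L]
  setattr(out, "flagged", nrow(out) == 0L)
  out[]
}
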