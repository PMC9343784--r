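#' Benchmark called DMRs against a spiked truth set
#'
#' Sensitivity is the fraction of truth regions overlapped (>= 1 bp) by at
#' least one called DMR, optionally requiring the direction to match; the
#' false-discovery proportion is the fraction of called DMRs overlapping no
#' truth region. The bp-level Jaccard index of the two interval sets is
#' also reported.
#'
#' @param dmrs a [call_dmrs()] table.
#' @param truth data.table chrom, start, end, direction (e.g. a
#'   [spike_differential_regions()] result filtered to the factors the
#'   contrast can detect).
#' @param match_direction require hyper/hypo agreement for a hit.
#' @return list: sensitivity, fdp, n_truth, n_called, jaccard.
#' @export
dmr_benchmark <- function(dmrs, truth, match_direction = TRUE) {
  d <- as.data.table(dmrs)
  t <- as.data.table(truth)
  hit_truth <- logical(nrow(t))
  hit_call <- logical(nrow(d))
  if (nrow(d) && nrow(t)) {
    for (i in seq_len(nrow(t))) {
      ov <- d$chrom == t$chrom[i] & d$start < t$end[i] & d$end > t$start[i]
      if (match_direction && "direction" %in% names(t)) {
        ov <- ov & d$direction == t$direction[i]
      }
      hit_truth[i] <- any(ov)
      hit_call <- hit_call | ov
    }
    # a called DMR overlapping any truth region (either direction) is not a
    # false discovery for FDP purposes
    for (j in seq_len(nrow(d))) {
      if (!hit_call[j]) {
        hit_call[j] <- any(t$chrom == d$chrom[j] & t$start < d$end[j] &
                             t$end > d$start[j])
      }
    }
  }
  jac <- .interval_jaccard(d, t)
  list(
    sensitivity = if (nrow(t)) mean(hit_truth) else NA_real_,
    fdp = if (nrow(d)) mean(!hit_call) else 0,
    n_truth = nrow(t), n_called = nrow(d), jaccard = jac
  )
}

# bp-level Jaccard of two interval sets
.interval_jaccard <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0)
  cov_bp <- function(dt, chroms) {
    lapply(chroms, function(ch) {
      x <- dt[chrom == ch][order(start)]
      if (!nrow(x)) return(integer(0))
      unlist(lapply(seq_len(nrow(x)), function(i) x$start[i]:(x$end[i] - 1L)))
    })
  }
  chroms <- union(unique(a$chrom), unique(b$chrom))
  ca <- cov_bp(as.data.table(a), chroms)
  cb <- cov_bp(as.data.table(b), chroms)
  inter <- sum(vapply(seq_along(chroms), function(i) {
    length(intersect(ca[[i]], cb[[i]]))
  }, numeric(1)))
  uni <- sum(vapply(seq_along(chroms), function(i) {
    length(union(ca[[i]], cb[[i]]))
  }, numeric(1)))
  if (uni == 0) 0 else inter / uni
}
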