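#' Bin coordinates for one gene's meta-gene axis
#'
#' The axis runs from `flank` bp upstream of the TSS, across the gene body
#' rescaled to `n_body_bins` equal-width bins, to `flank` bp downstream of
#' the TTS. Flank bins have fixed width `flank / n_flank_bins` (100 bp by
#' default). For minus-strand genes the bin order is reversed so that bin 0
#' is always the biological upstream end; minus-strand body bin boundaries
#' are the exact mirror of the plus-strand ones. Flank bins clipped at a
#' chromosome edge are flagged partial (and dropped when fully outside).
#'
#' @param gene list or one-row data.frame with chrom, start, end, strand
#'   (0-based half-open).
#' @param chrom_length chromosome length in bp.
#' @param flank flank extent in bp (default 5000).
#' @param n_flank_bins,n_body_bins bin counts per flank / for the body.
#' @return data.table bin, role (upstream/body/downstream), start, end,
#'   partial — or NULL when the gene body is shorter than `n_body_bins` bp.
#' @export
gene_bin_coordinates <- function(gene, chrom_length, flank = 5000L,
                                 n_flank_bins = 50L, n_body_bins = 60L) {
  len <- gene$end - gene$start
  if (len < n_body_bins) return(NULL)
  w <- flank / n_flank_bins
  # plus-orientation boundaries
  up_start <- gene$start - flank + w * (seq_len(n_flank_bins) - 1)
  body_bounds <- gene$start + round(len * (0:n_body_bins) / n_body_bins)
  down_start <- gene$end + w * (seq_len(n_flank_bins) - 1)
  bins <- data.table(
    start = c(up_start, body_bounds[-(n_body_bins + 1L)], down_start),
    end = c(up_start + w, body_bounds[-1L], down_start + w),
    role = rep(c("upstream", "body", "downstream"),
               c(n_flank_bins, n_body_bins, n_flank_bins))
  )
  if (identical(gene$strand, "-")) {
    # reverse the axis: bin 0 becomes the genomically rightmost interval
    bins <- bins[rev(seq_len(nrow(bins)))]
    bins[, role := rep(c("upstream", "body", "downstream"),
                       c(n_flank_bins, n_body_bins, n_flank_bins))]
  }
  bins[, bin := seq_len(.N) - 1L]
  clipped_s <- pmax(bins$start, 0)
  clipped_e <- pmin(bins$end, chrom_length)
  bins[, partial := clipped_s != start | clipped_e != end]
  bins[, `:=`(start = as.numeric(clipped_s), end = as.numeric(clipped_e))]
  bins <- bins[end > start]
  bins[, .(bin, role, start, end, partial)]
}

#' Averaged meta-gene methylation profile
#'
#' For every gene the sites falling in each bin contribute a
#' coverage-weighted mean of the site value (a methylation level or a
#' difference); bins are then aggregated over all genes. A site overlapping
#' several genes contributes to each. Genes with a body shorter than
#' `n_body_bins` bp are skipped with a warning; empty bins are missing.
#'
#' @param site_table data.table with chrom, start, value and weight columns.
#' @param genes data.table gene_id, chrom, start, end, strand.
#' @param chrom_lengths named integer vector.
#' @param value_col,weight_col column names in `site_table` holding the
#'   per-site value and weight (weights of 1 give unweighted means).
#' @param flank,n_flank_bins,n_body_bins axis geometry, see
#'   [gene_bin_coordinates()].
#' @return data.table of class `metagene_profile`: bin, role, mean,
#'   n_sites; `2 * n_flank_bins + n_body_bins` rows.
#' @export
average_profile <- function(site_table, genes, chrom_lengths,
                            value_col = "value", weight_col = "weight",
                            flank = 5000L, n_flank_bins = 50L,
                            n_body_bins = 60L) {
  genes <- as.data.table(genes)
  if (!nrow(genes)) stop("no genes supplied")
  sites <- as.data.table(site_table)
  stopifnot(value_col %in% names(sites), weight_col %in% names(sites))
  n_bins <- 2L * n_flank_bins + n_body_bins
  acc_wv <- numeric(n_bins)
  acc_w <- numeric(n_bins)
  acc_n <- integer(n_bins)
  skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    bins <- gene_bin_coordinates(g, chrom_lengths[[g$chrom]], flank,
                                 n_flank_bins, n_body_bins)
    if (is.null(bins)) { skipped <- skipped + 1L; next }
    s <- sites[chrom == g$chrom &
                 start >= min(bins$start) & start < max(bins$end)]
    if (!nrow(s)) next
    for (j in seq_len(nrow(bins))) {
      idx <- s$start >= bins$start[j] & s$start < bins$end[j]
      if (!any(idx)) next
      b <- bins$bin[j] + 1L
      wts <- s[[weight_col]][idx]
      acc_wv[b] <- acc_wv[b] + sum(wts * s[[value_col]][idx])
      acc_w[b] <- acc_w[b] + sum(wts)
      acc_n[b] <- acc_n[b] + sum(idx)
    }
  }
  if (skipped > 0L) {
    warning(skipped, " gene(s) shorter than ", n_body_bins, " bp skipped")
  }
  out <- data.table(
    bin = 0:(n_bins - 1L),
    role = rep(c("upstream", "body", "downstream"),
               c(n_flank_bins, n_body_bins, n_flank_bins)),
    mean = ifelse(acc_w > 0, acc_wv / acc_w, NA_real_),
    n_sites = acc_n
  )
  structure(out, class = c("metagene_profile", class(out)))
}
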