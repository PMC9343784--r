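# site keys used to match CpGs between contrasts
.site_keys <- function(tab, significant = TRUE) {
  dt <- as.data.table(tab)
  if (significant && "sig" %in% names(dt)) dt <- dt[sig == TRUE]
  paste(dt$chrom, dt$start, dt$strand, sep = ":")
}

#' Venn partition and hypergeometric overlap of two DMC sets
#'
#' Counts sites unique to each contrast and in common, and tests overlap
#' enrichment with an upper-tail hypergeometric p-value:
#' `P[X >= n_common]` for `X ~ Hypergeom(N = universe, K = |A|, n = |B|)`.
#' The universe is the number of sites tested in both contrasts (the most
#' conservative defensible choice; pass your own count to change it).
#'
#' @param dmcs_A,dmcs_B [call_dmcs()] tables (their significant sites are
#'   used) or character vectors of site keys.
#' @param universe integer count of sites tested in both contrasts.
#' @return object of class `overlap_result`: list with n_A_only, n_B_only,
#'   n_common, universe, p_overlap.
#' @export
dmc_set_overlap <- function(dmcs_A, dmcs_B, universe) {
  a <- if (is.character(dmcs_A)) unique(dmcs_A) else .site_keys(dmcs_A)
  b <- if (is.character(dmcs_B)) unique(dmcs_B) else .site_keys(dmcs_B)
  universe <- as.integer(universe)
  if (universe < length(a) || universe < length(b)) {
    stop("universe (", universe, ") smaller than a DMC set (",
         length(a), ", ", length(b), ")")
  }
  n_common <- length(intersect(a, b))
  p <- phyper(n_common - 1L, length(a), universe - length(a), length(b),
              lower.tail = FALSE)
  structure(list(n_A_only = length(a) - n_common,
                 n_B_only = length(b) - n_common,
                 n_common = n_common, universe = universe, p_overlap = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap: A-only", x$n_A_only, "| common", x$n_common, "| B-only",
      x$n_B_only, "of", x$universe, "; p =", format(x$p_overlap), "\n")
  invisible(x)
}

#' Pearson correlation of methylation differences between two contrasts
#'
#' Pairs per-site differences (percentage points) from the two full tested
#' tables at shared site keys. `scope = "union"` uses sites flagged DMC in
#' either contrast (the literal reading of "all CpG sites that were
#' differentially methylated in" either condition); `scope = "common"` uses
#' sites significant in both.
#'
#' @param contrast_A_table,contrast_B_table [call_dmcs()] tables.
#' @param site_scope `"union"` or `"common"`.
#' @return object of class `correlation_result`: list with r, p (two-sided,
#'   from the t transform; NA when fewer than 3 sites), n_sites, site_scope.
#' @export
correlate_deltas <- function(contrast_A_table, contrast_B_table,
                             site_scope = c("union", "common")) {
  site_scope <- match.arg(site_scope)
  a <- as.data.table(contrast_A_table)[
    , .(chrom, start, strand, delta_A = delta_pp, sig_A = sig)]
  b <- as.data.table(contrast_B_table)[
    , .(chrom, start, strand, delta_B = delta_pp, sig_B = sig)]
  m <- merge(a, b, by = c("chrom", "start", "strand"))
  m <- if (site_scope == "union") m[sig_A | sig_B] else m[sig_A & sig_B]
  n <- nrow(m)
  if (n < 2L) {
    return(structure(list(r = NA_real_, p = NA_real_, n_sites = n,
                          site_scope = site_scope),
                     class = "correlation_result"))
  }
  r <- cor(m$delta_A, m$delta_B)
  p <- if (n >= 3L && is.finite(r) && abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  } else if (n >= 3L && is.finite(r)) 0 else NA_real_
  structure(list(r = r, p = p, n_sites = n, site_scope = site_scope),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Pearson r =", format(x$r, digits = 4), "(", x$site_scope, "scope,",
      x$n_sites, "sites ), p =", format(x$p), "\n")
  invisible(x)
}

#' Per-sample methylation-level matrix at given sites
#'
#' Builds the sites x samples matrix of methylation levels used for
#' z-scoring and clustering heatmaps.
#'
#' @param counts named list of per-sample count tables.
#' @param site_keys character vector `"chrom:start:strand"` selecting rows.
#' @param fill `"na"` (default) or `"zero"` for sites without coverage in a
#'   sample.
#' @return numeric matrix, rownames = site keys, colnames = sample ids.
#' @export
methylation_matrix <- function(counts, site_keys, fill = c("na", "zero")) {
  fill <- match.arg(fill)
  m <- matrix(if (fill == "na") NA_real_ else 0,
              nrow = length(site_keys), ncol = length(counts),
              dimnames = list(site_keys, names(counts)))
  for (sid in names(counts)) {
    dt <- counts[[sid]]
    keys <- paste(dt$chrom, dt$start, dt$strand, sep = ":")
    idx <- match(site_keys, keys)
    cov <- dt$count_m[idx] + dt$count_u[idx]
    lev <- ifelse(!is.na(cov) & cov > 0, dt$count_m[idx] / cov,
                  if (fill == "na") NA_real_ else 0)
    m[, sid] <- lev
  }
  m
}

#' Row-wise z-score normalisation
#'
#' Standardises each row (site) to mean 0 and unit variance. Constant rows
#' (or rows with missing values) carry no clustering information and are
#' dropped with a warning.
#'
#' @param m numeric matrix, sites x samples.
#' @return z-scored matrix (possibly with fewer rows).
#' @export
zscore_matrix <- function(m) {
  stopifnot(is.matrix(m))
  sds <- apply(m, 1L, sd)
  keep <- is.finite(sds) & sds > 0
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " constant or incomplete rows")
    m <- m[keep, , drop = FALSE]
    sds <- sds[keep]
  }
  t(scale(t(m)))[, , drop = FALSE]
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the matrix columns with Euclidean distance
#' and complete linkage (the pheatmap default).
#'
#' @param m numeric matrix with at least two columns.
#' @return list with `order` (leaf order, column indices), `labels`,
#'   `merge`, `height` and the underlying `hclust` object.
#' @export
hclust_order <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  hc <- hclust(dist(t(m), method = "euclidean"), method = "complete")
  list(order = hc$order, labels = colnames(m), merge = hc$merge,
       height = hc$height, hclust = hc)
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, tests over-representation of the query genes with an
#' upper-tail hypergeometric p (`P[X >= k]`), BH-adjusts across sets and
#' sorts by ascending p. Sets are intersected with the universe first.
#'
#' @param query_genes character vector; must be a subset of
#'   `universe_genes`.
#' @param gmt named list of gene sets (see [read_gmt()]).
#' @param universe_genes character vector of all eligible genes.
#' @param top_n optionally return only the first `top_n` rows.
#' @return data.table: set, k (overlap), K (set size in universe),
#'   n (query size), N (universe size), p, q.
#' @export
enrich_gene_sets <- function(query_genes, gmt, universe_genes, top_n = Inf) {
  universe_genes <- unique(universe_genes)
  if (!length(universe_genes)) stop("empty universe")
  query_genes <- unique(query_genes)
  if (length(setdiff(query_genes, universe_genes))) {
    stop("query genes must be a subset of the universe")
  }
  N <- length(universe_genes)
  n <- length(query_genes)
  rows <- lapply(names(gmt), function(s) {
    members <- intersect(gmt[[s]], universe_genes)
    K <- length(members)
    k <- length(intersect(members, query_genes))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.table(set = s, k = k, K = K, n = n, N = N, p = p)
  })
  out <- rbindlist(rows)
  out[, q := bh_adjust(p)]
  setorder(out, p, set)
  if (is.finite(top_n)) out <- head(out, top_n)
  out[]
}
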