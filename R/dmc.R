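#' Define a two-group contrast
#'
#' The convention follows the study design: group A is the control listed
#' first, group B the treatment; reported differences are B minus A.
#'
#' @param name contrast label, e.g. `"SAL_SAL-vs-METH_SAL"`.
#' @param group_A,group_B character vectors of sample ids; must be disjoint
#'   and non-empty.
#' @return object of class `contrast`.
#' @export
contrast <- function(name, group_A, group_B) {
  if (!length(group_A) || !length(group_B)) {
    stop("contrast groups must be non-empty")
  }
  if (length(intersect(group_A, group_B))) {
    stop("contrast groups must be disjoint")
  }
  structure(list(name = name, group_A = group_A, group_B = group_B),
            class = "contrast")
}

#' Pool replicate counts within a group
#'
#' Sums methylated/unmethylated counts per site over the given samples
#' (outer union over sites: a site missing from one replicate contributes
#' zero). Replicates are pooled before testing, matching the study's
#' combine-then-test strategy.
#'
#' @param counts named list of per-sample count tables (see
#'   [read_cytosine_report()]).
#' @param samples sample ids to pool.
#' @return data.table chrom, start, strand, context, count_m, count_u,
#'   sorted by position.
#' @export
pool_group_counts <- function(counts, samples) {
  if (!length(samples)) stop("empty sample list")
  missing <- setdiff(samples, names(counts))
  if (length(missing)) {
    stop("samples not found in counts: ", paste(missing, collapse = ", "))
  }
  pooled <- rbindlist(counts[samples])[
    , .(count_m = sum(count_m), count_u = sum(count_u)),
    by = .(chrom, start, strand, context)]
  setorder(pooled, chrom, start, strand)
  pooled[]
}

#' Two-sided Fisher exact test on 2x2 methylation tables (vectorised)
#'
#' For each site the table is (meth_A, unmeth_A) vs (meth_B, unmeth_B). The
#' two-sided p-value sums all hypergeometric table probabilities not
#' exceeding the observed one (with the standard `1 + 1e-7` relative
#' tolerance). Degenerate tables (a zero margin, including the all-zero
#' table) return p = 1.
#'
#' @param meth_A,unmeth_A,meth_B,unmeth_B non-negative integer vectors of
#'   equal length.
#' @return numeric vector of p-values in (0, 1].
#' @export
fisher_dmc_test <- function(meth_A, unmeth_A, meth_B, unmeth_B) {
  n <- length(meth_A)
  stopifnot(length(unmeth_A) == n, length(meth_B) == n, length(unmeth_B) == n)
  if (any(c(meth_A, unmeth_A, meth_B, unmeth_B) < 0)) {
    stop("counts must be non-negative")
  }
  vapply(seq_len(n), function(i) {
    a <- meth_A[i]; b <- unmeth_A[i]; c_ <- meth_B[i]; d <- unmeth_B[i]
    N <- a + b + c_ + d
    K <- a + c_          # methylated margin
    m <- a + b           # group A margin
    if (N == 0 || K == 0 || K == N || m == 0 || m == N) return(1)
    lo <- max(0, m + K - N)
    hi <- min(K, m)
    dens <- dhyper(lo:hi, K, N - K, m)
    p_obs <- dhyper(a, K, N - K, m)
    min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")`, kept as a named
#' step so the FDR procedure used across the pipeline is explicit and
#' swappable.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Call differentially methylated cytosines for a contrast
#'
#' Pools replicates per group, keeps CpG-context sites whose pooled
#' coverage is strictly greater than `min_cov` in BOTH groups, tests each
#' with a two-sided Fisher exact test, and BH-adjusts over the tested
#' sites. The returned table keeps all tested sites (downstream analyses
#' need non-significant deltas too) with a `sig` flag at `q <= q_max`.
#'
#' @param counts named list of per-sample count tables.
#' @param contrast a [contrast()].
#' @param min_cov pooled per-group coverage filter; strict (`> min_cov`).
#' @param q_max significance threshold on the BH q-value.
#' @return data.table of class `dmc_table`: chrom, start, strand, m_A, m_B,
#'   delta_pp (percentage points, B minus A), cov_A, cov_B, p, q, sig.
#'   Attributes: `contrast`, `q_max`, `n_input_sites`.
#' @export
call_dmcs <- function(counts, contrast, min_cov = 10L, q_max = 0.05) {
  stopifnot(inherits(contrast, "contrast"))
  pa <- pool_group_counts(counts, contrast$group_A)[context == "CpG"]
  pb <- pool_group_counts(counts, contrast$group_B)[context == "CpG"]
  n_input <- length(unique(c(
    paste(pa$chrom, pa$start, pa$strand),
    paste(pb$chrom, pb$start, pb$strand))))
  merged <- merge(
    pa[, .(chrom, start, strand, m_cnt_A = count_m, u_cnt_A = count_u)],
    pb[, .(chrom, start, strand, m_cnt_B = count_m, u_cnt_B = count_u)],
    by = c("chrom", "start", "strand")
  )
  merged[, `:=`(cov_A = m_cnt_A + u_cnt_A, cov_B = m_cnt_B + u_cnt_B)]
  tested <- merged[cov_A > min_cov & cov_B > min_cov]
  if (!nrow(tested)) {
    stop("contrast ", contrast$name, ": no usable sites after the ",
         "coverage filter (> ", min_cov, "x in both groups)")
  }
  tested[, `:=`(m_A = m_cnt_A / cov_A, m_B = m_cnt_B / cov_B)]
  tested[, delta_pp := (m_B - m_A) * 100]
  tested[, p := fisher_dmc_test(m_cnt_A, u_cnt_A, m_cnt_B, u_cnt_B)]
  tested[, q := bh_adjust(p)]
  tested[, sig := q <= q_max]
  out <- tested[, .(chrom, start, strand, m_A, m_B, delta_pp,
                    cov_A, cov_B, p, q, sig)]
  setorder(out, chrom, start, strand)
  setattr(out, "contrast", contrast$name)
  setattr(out, "q_max", q_max)
  setattr(out, "n_input_sites", n_input)
  setattr(out, "class", c("dmc_table", class(out)))
  out[]
}

#' Per-context global methylation summary
#'
#' Weighted mean methylation level (total methylated / total reads) and
#' site-count frequency per cytosine context, per sample or for a single
#' table. A context with zero coverage gets a missing level.
#'
#' @param counts a single count table or a named list of them.
#' @return data.table with columns (sample,) context, n_sites, frequency,
#'   level; frequencies sum to 1 within each sample.
#' @export
context_methylation_summary <- function(counts) {
  summarise_one <- function(dt) {
    s <- as.data.table(dt)[, .(
      n_sites = .N,
      total_m = sum(count_m),
      total = sum(count_m + count_u)
    ), by = context]
    s[, frequency := n_sites / sum(n_sites)]
    s[, level := ifelse(total > 0, total_m / total, NA_real_)]
    s[, .(context, n_sites, frequency, level)]
  }
  if (is.data.frame(counts)) return(summarise_one(counts))
  rbindlist(lapply(names(counts), function(sid) {
    cbind(data.table(sample = sid), summarise_one(counts[[sid]]))
  }))
}
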