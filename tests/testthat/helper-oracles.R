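# Independent brute-force oracles used to verify the analytical routines.
# They deliberately avoid the code paths (and distribution functions) used
# by the implementation.

# two-sided Fisher exact p by full enumeration over tables with fixed
# margins, hypergeometric masses built from choose()
oracle_fisher <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + c_
  m <- a + b
  if (N == 0 || K == 0 || K == N || m == 0 || m == N) return(1)
  ks <- max(0, m + K - N):min(K, m)
  mass <- choose(K, ks) * choose(N - K, m - ks) / choose(N, m)
  p_obs <- choose(K, a) * choose(N - K, m - a) / choose(N, m)
  min(1, sum(mass[mass <= p_obs * (1 + 1e-7)]))
}

# literal Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# upper-tail hypergeometric P[X >= k] by pmf summation
oracle_hyper_upper <- function(k, K, n, N) {
  ks <- max(k, max(0, n + K - N)):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks) / choose(N, n))
}

# O(n^3) complete-linkage agglomeration over matrix columns; returns merge
# heights in merge order
oracle_hclust_complete <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) d[i, j] <- sqrt(sum((m[, i] - m[, j])^2))
  }
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  heights <- numeric(0)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); best_h <- Inf
    idx <- which(active)
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        a <- clusters[[idx[ii]]]; b <- clusters[[idx[jj]]]
        h <- max(d[a, b, drop = FALSE])
        if (h < best_h - 1e-12) {
          best_h <- h; best <- c(idx[ii], idx[jj])
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active[best[2]] <- FALSE
  }
  heights
}
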