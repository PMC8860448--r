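# independent oracles: deliberately naive implementations used only to
# verify the package's computations

# Benjamini-Hochberg by the literal step-up definition:
# q_i = min over j with p_(j) >= p_(i) of m * p_(j) / rank_j, capped at 1
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- q
  out
}

# upper-tail hypergeometric by enumeration over overlap sizes
hyper_bruteforce <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# O(n^3) average-linkage agglomeration returning sorted merge heights
avg_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# boolean formulas of the two filtering cascades, evaluated directly
vm_pass_formula <- function(r1, r2a, r2b, r3) r1 && (r2a || r2b) && !r3
str_pass_formula <- function(r1, r2a, r2b, r2c, r3a, r3b, r4) {
  r1 && (r2a || r2b || r2c) && (r3a || r3b) && !r4
}
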