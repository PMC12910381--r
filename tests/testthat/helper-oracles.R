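# Independent brute-force oracles used to cross-check the package's
# computations. Deliberately naive implementations.

# Benjamini-Hochberg step-up, written directly from the definition.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(q)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Classic quantile normalization for complete matrices without ties.
quantile_norm_brute <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(col) ref[rank(col)])
  dimnames(out) <- dimnames(m)
  out
}

# Naive average-linkage agglomeration; returns the cophenetic distance matrix.
average_linkage_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    a <- clusters[[best[1L]]]; b <- clusters[[best[2L]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1L]]] <- c(a, b)
    clusters[[best[2L]]] <- NULL
  }
  coph
}

# Sample-space PCA by eigendecomposition of the covariance of centered data.
pca_eigen_brute <- function(v) {
  x <- t(v)
  x <- sweep(x, 2L, colMeans(x))
  e <- eigen(stats::cov(x), symmetric = TRUE)
  list(scores = x %*% e$vectors,
       var_explained = pmax(e$values, 0) / sum(pmax(e$values, 0)))
}

# Hypergeometric upper tail by direct enumeration of the pmf.
hyper_tail_brute <- function(k, n_term, n_bg, n_draw) {
  j <- k:min(n_term, n_draw)
  sum(choose(n_term, j) * choose(n_bg - n_term, n_draw - j)) / choose(n_bg, n_draw)
}
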