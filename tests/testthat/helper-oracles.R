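# Independent brute-force oracles used to validate the graph metrics.
# These deliberately avoid the package's own (bitset/BFS) code paths.

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- rbinom(length(ut), 1, p)
  A + t(A)
}

# clustering by enumeration of all node triples
oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        links <- links + A[nb[a], nb[b]]
    2 * links / (k * (k - 1))
  })
}

# all-pairs shortest paths by Floyd-Warshall
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_path_metrics <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(A)
  off <- row(D) != col(D)
  inv <- ifelse(is.infinite(D), 0, 1 / D)
  finite_off <- off & is.finite(D)
  list(
    lp = if (any(finite_off)) mean(D[finite_off]) else NA_real_,
    eglob = sum(inv[off]) / (n * (n - 1)),
    enod = sapply(seq_len(n), function(i) mean(inv[i, -i]))
  )
}

# local efficiency by explicit induced-subgraph reconstruction
oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    D <- oracle_distances(sub)
    off <- row(D) != col(D)
    inv <- ifelse(is.infinite(D), 0, 1 / D)
    sum(inv[off]) / (k * (k - 1))
  })
}

# ROC AUC by exhaustive positive x negative pair counting (ties = 1/2)
oracle_auc_pairs <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up, written independently of p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# small deterministic ROI series for prep/fc tests
toy_series <- function(t_len = 60, n = 5, seed = 1, tr = 2) {
  set.seed(seed)
  roi_time_series(matrix(rnorm(t_len * n), t_len, n,
                         dimnames = list(NULL, seq_len(n))),
                  "toy", "control", tr)
}
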