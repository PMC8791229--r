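triangle <- function() {
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 3] <- A[1, 3] <- 1L; A + t(A)
}
path3 <- function() {
  A <- matrix(0L, 3, 3); A[1, 2] <- A[2, 3] <- 1L; A + t(A)
}
complete_graph <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}
star_graph <- function(n) {
  A <- matrix(0L, n, n); A[1, 2:n] <- 1L; A + t(A)
}
ring_lattice <- function(n, k) {
  A <- matrix(0L, n, n)
  for (d in seq_len(k / 2)) {
    idx <- cbind(seq_len(n), (seq_len(n) + d - 1) %% n + 1)
    A[idx] <- 1L
    A[idx[, 2:1]] <- 1L
  }
  A
}

test_that("clustering, paths and efficiencies are exact on canonical graphs", {
  expect_equal(clustering_coefficient(triangle())$cp, 1)
  expect_equal(clustering_coefficient(path3())$cp, 0)

  k4 <- shortest_path_metrics(complete_graph(4))
  expect_equal(k4$lp, 1)
  expect_equal(k4$eglob, 1)
  expect_equal(k4$enod, rep(1, 4))
  expect_equal(local_efficiency(complete_graph(4))$eloc, 1)
  expect_equal(clustering_coefficient(complete_graph(4))$cp, 1)

  p3 <- shortest_path_metrics(path3())
  expect_equal(p3$enod[1], 0.75)       # (1 + 1/2) / 2
  expect_equal(p3$lp, 4 / 3)           # pairs at distance 1,1,2
  expect_equal(p3$eglob, 5 / 6)

  expect_equal(local_efficiency(star_graph(6))$eloc, 0)
})

test_that("all metrics match brute-force oracles exactly on random graphs", {
  for (i in 1:10) {
    A <- random_graph(sample(6:15, 1), runif(1, 0.2, 0.6), seed = 100 + i)
    expect_equal(clustering_coefficient(A)$per_node, oracle_clustering(A))
    om <- oracle_path_metrics(A)
    pm <- suppressWarnings(shortest_path_metrics(A))
    D <- oracle_distances(A)
    Dp <- pm$distances; Dp[Dp == -1] <- Inf
    expect_equal(Dp, D, ignore_attr = TRUE)
    expect_equal(pm$lp, om$lp)
    expect_equal(pm$eglob, om$eglob)
    expect_equal(pm$enod, om$enod)
    expect_equal(local_efficiency(A)$per_node, oracle_local_efficiency(A))
  }
})

test_that("edgeless and disconnected graphs use the documented conventions", {
  empty <- matrix(0L, 5, 5)
  expect_warning(pm <- shortest_path_metrics(empty), "no edges")
  expect_true(is.na(pm$lp))
  expect_equal(pm$eglob, 0)
  expect_equal(pm$enod, rep(0, 5))

  two_comp <- matrix(0L, 4, 4)
  two_comp[1, 2] <- two_comp[2, 1] <- two_comp[3, 4] <- two_comp[4, 3] <- 1L
  expect_warning(pm2 <- shortest_path_metrics(two_comp), "disconnected")
  expect_equal(pm2$lp, 1)            # connected pairs only
  expect_equal(pm2$eglob, 4 / 12)
})

test_that("degree-preserving rewiring keeps degrees and randomizes lattices", {
  for (i in 1:10) {
    A <- random_graph(20, 0.3, seed = 200 + i)
    B <- rewire_preserving_degree(A, null_model_config(seed = i))
    expect_identical(rowSums(B), rowSums(A))
    expect_true(all(diag(B) == 0))
    expect_equal(B, t(B), ignore_attr = TRUE)
  }
  # a triangle admits no valid swap
  expect_message(B <- rewire_preserving_degree(triangle(),
                                               null_model_config(seed = 1)),
                 "unchanged")
  expect_equal(as.integer(B), as.integer(triangle()))
  # rewiring destroys lattice clustering
  L <- ring_lattice(30, 4)
  cp0 <- clustering_coefficient(L)$cp
  cps <- sapply(1:20, function(i) {
    B <- rewire_preserving_degree(L, null_model_config(swaps_per_edge = 10,
                                                       seed = 300 + i))
    clustering_coefficient(B)$cp
  })
  expect_lt(mean(cps), cp0)
})

test_that("small-world normalization is calibrated", {
  # degenerate config: zero swap attempts leave the nulls identical
  L <- ring_lattice(30, 4)
  sw <- small_world_normalize(L, null_model_config(n_random = 5,
                                                   swaps_per_edge = 0, seed = 1))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda_norm, 1)
  expect_equal(sw$sigma, 1)

  # Watts-Strogatz graph at connectome-like density is small-world
  set.seed(42)
  ws <- igraph::sample_smallworld(1, 160, 6, 0.1)
  A <- as.matrix(igraph::as_adjacency_matrix(ws, sparse = FALSE))
  storage.mode(A) <- "integer"
  sw2 <- small_world_normalize(A, null_model_config(n_random = 50, seed = 2))
  expect_gt(sw2$sigma, 1)
  expect_gt(sw2$gamma, 1)

  # an Erdos-Renyi graph is its own null: gamma and sigma near 1
  set.seed(7)
  er <- igraph::sample_gnp(200, 0.05)
  Aer <- as.matrix(igraph::as_adjacency_matrix(er, sparse = FALSE))
  storage.mode(Aer) <- "integer"
  sw3 <- small_world_normalize(Aer, null_model_config(n_random = 100, seed = 3))
  expect_lt(abs(sw3$gamma - 1), 0.15)
  expect_lt(abs(sw3$sigma - 1), 0.15)
})

test_that("rewiring and null metrics are seed-deterministic", {
  A <- random_graph(25, 0.3, seed = 9)
  cfg <- null_model_config(n_random = 3, seed = 77)
  expect_identical(rewire_preserving_degree(A, cfg),
                   rewire_preserving_degree(A, cfg))
  s1 <- small_world_normalize(A, cfg)
  s2 <- small_world_normalize(A, cfg)
  expect_identical(s1, s2)
})

test_that("AUC over sparsity integrates exactly", {
  grid <- sparsity_grid(0.10, 0.34, 0.01)
  expect_equal(auc_over_sparsity(rep(3, 25), grid), 0.24 * 3)
  vals <- 2 + 5 * grid$thresholds  # linear in s: closed form
  exact <- 2 * 0.24 + 5 * (0.34^2 - 0.10^2) / 2
  expect_lt(abs(auc_over_sparsity(vals, grid) - exact), 1e-12)
  expect_error(auc_over_sparsity(c(1, NaN, rep(1, 23)), grid), "finite")
  expect_error(auc_over_sparsity(1, 0.1), "at least 2")
})

test_that("adding an edge never decreases global or nodal efficiency", {
  for (i in 1:20) {
    A <- random_graph(12, 0.25, seed = 400 + i)
    free <- which(A == 0 & upper.tri(A))
    if (!length(free)) next
    pick <- free[sample.int(length(free), 1)]
    B <- A
    B[pick] <- 1L
    B[cbind(col(A)[pick], row(A)[pick])] <- 1L
    pa <- suppressWarnings(shortest_path_metrics(A))
    pb <- suppressWarnings(shortest_path_metrics(B))
    expect_gte(pb$eglob, pa$eglob)
    expect_true(all(pb$enod >= pa$enod - 1e-15))
  }
})

test_that("metric curves over a stack of complete graphs give flat unit AUCs", {
  n <- 10
  grid <- sparsity_grid(0.10, 0.34, 0.06)
  adj <- replicate(length(grid$thresholds), complete_graph(n), simplify = FALSE)
  stack <- structure(list(subject_id = "k", thresholds = grid$thresholds,
                          adjacency = adj), class = "graph_stack")
  mc <- compute_all_metrics(stack, grid, NULL)
  expect_equal(unname(mc$auc_global["eglob"]), 0.24)
  expect_equal(unname(mc$auc_global["eloc"]), 0.24)
  expect_equal(dim(mc$nodal), c(5, n))
  expect_equal(unname(mc$auc_nodal), rep(0.24, n))
})

test_that("compute_all_metrics is deterministic for fixed seeds", {
  s <- toy_series(t_len = 80, n = 24, seed = 13)
  stack <- binarize_stack(compute_fc(s), sparsity_grid(0.10, 0.34, 0.06))
  cfg <- null_model_config(n_random = 5, seed = 55)
  m1 <- suppressWarnings(compute_all_metrics(stack, sparsity_grid(0.10, 0.34, 0.06), cfg))
  m2 <- suppressWarnings(compute_all_metrics(stack, sparsity_grid(0.10, 0.34, 0.06), cfg))
  expect_identical(m1$global$sigma, m2$global$sigma)
})
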