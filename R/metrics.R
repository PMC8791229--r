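#' Clustering coefficient
#'
#' Per-node clustering `2 e_i / (k_i (k_i - 1))` (0 for degree < 2), where
#' `e_i` counts edges among node i's neighbours, and the network mean Cp.
#'
#' @param adjacency Binary symmetric matrix with zero diagonal.
#' @return List with `per_node` (numeric vector) and `cp` (mean).
#' @export
clustering_coefficient <- function(adjacency) {
  adjacency <- check_adjacency(adjacency)
  per_node <- cpp_clustering(adjacency)
  list(per_node = per_node, cp = mean(per_node))
}

#' Shortest-path metrics of a binary graph
#'
#' Breadth-first hop distances give the characteristic path length Lp (mean
#' distance over *connected* ordered pairs, excluding i = j; a warning is
#' issued when disconnected pairs exist and `NA` returned for an edgeless
#' graph), global efficiency Eglob (mean of 1/d over all ordered pairs with
#' 1/Inf = 0) and per-node nodal efficiency Enod(i) (mean of 1/d(i,j) over
#' j != i).
#'
#' @param adjacency Binary symmetric matrix with zero diagonal.
#' @return List with `distances` (integer matrix, -1 = unreachable), `lp`,
#'   `eglob`, `enod`, `n_disconnected_pairs`.
#' @export
shortest_path_metrics <- function(adjacency) {
  adjacency <- check_adjacency(adjacency)
  pm <- cpp_path_metrics(adjacency)
  if (pm$unreached_pairs > 0) {
    if (is.na(pm$lp))
      warning("graph has no edges; Lp undefined (NA)", call. = FALSE)
    else
      warning(sprintf("%d disconnected ordered pairs excluded from Lp",
                      as.integer(pm$unreached_pairs)), call. = FALSE)
  }
  list(distances = cpp_bfs_distances(adjacency), lp = pm$lp,
       eglob = pm$eglob, enod = pm$enod,
       n_disconnected_pairs = as.integer(pm$unreached_pairs))
}

#' Local efficiency
#'
#' Per-node local efficiency: the global efficiency of the subgraph induced
#' by the node's neighbours with the node itself removed (0 for degree < 2),
#' and the network mean Eloc.
#'
#' @param adjacency Binary symmetric matrix with zero diagonal.
#' @return List with `per_node` and `eloc` (mean).
#' @export
local_efficiency <- function(adjacency) {
  adjacency <- check_adjacency(adjacency)
  per_node <- cpp_local_efficiency(adjacency)
  list(per_node = per_node, eloc = mean(per_node))
}

#' Null-model configuration
#'
#' Degree-preserving (Maslov-Sneppen) randomization settings used when
#' normalizing Cp and Lp against matched random networks.
#'
#' @param n_random Number of random networks (default 100).
#' @param swaps_per_edge Attempted swaps per edge (default 10; 0 is allowed
#'   as a degenerate identity rewiring useful for testing).
#' @param seed Integer seed; per-threshold substreams are derived from it.
#' @return Object of class `null_model_config`.
#' @export
null_model_config <- function(n_random = 100, swaps_per_edge = 10, seed = 1) {
  if (!is_count(n_random) || n_random < 1) stopf("n_random must be >= 1")
  if (!is.numeric(swaps_per_edge) || swaps_per_edge < 0)
    stopf("swaps_per_edge must be non-negative")
  structure(list(n_random = n_random, swaps_per_edge = swaps_per_edge,
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' Degree-preserving rewiring
#'
#' Randomizes a binary graph by repeated pairwise edge swaps
#' ((a,b),(c,d) -> (a,d),(c,b)) that preserve every node's degree exactly;
#' swaps creating self-loops or duplicate edges are rejected. The number of
#' attempted swaps is `swaps_per_edge * |E|`. Graphs admitting no valid swap
#' (e.g. a triangle) are returned unchanged with a message.
#'
#' @param adjacency Binary symmetric matrix with zero diagonal and >= 2 edges.
#' @param config A [null_model_config()]; its `seed` drives the swap stream.
#' @return Rewired adjacency matrix with attribute `n_swaps` (successful
#'   swap count).
#' @export
rewire_preserving_degree <- function(adjacency, config = null_model_config()) {
  adjacency <- check_adjacency(adjacency)
  if (sum(adjacency) / 2 < 2)
    stopf("need at least 2 edges to rewire")
  res <- cpp_rewire(adjacency, config$swaps_per_edge, config$seed)
  out <- res$adjacency
  dimnames(out) <- dimnames(adjacency)
  if (res$n_swaps == 0 && config$swaps_per_edge > 0)
    message("no valid degree-preserving swap found; returning the graph unchanged")
  attr(out, "n_swaps") <- as.integer(res$n_swaps)
  out
}

#' Small-world normalization against matched random networks
#'
#' Computes gamma = Cp_real / Cp_rand, lambda = Lp_real / Lp_rand and
#' sigma = gamma / lambda, where Cp_rand and Lp_rand are means over
#' `n_random` degree-preserving rewirings of the real graph. A network is
#' conventionally called small-world when gamma > 1 with lambda near 1,
#' i.e. sigma > 1.
#'
#' @param adjacency Real binary graph (>= 2 edges).
#' @param config A [null_model_config()].
#' @return List with `gamma`, `lambda_norm`, `sigma`, `cp_real`, `lp_real`,
#'   `cp_rand`, `lp_rand`. `gamma` is `NA` with a warning if the null mean
#'   clustering is zero.
#' @export
small_world_normalize <- function(adjacency, config = null_model_config()) {
  adjacency <- check_adjacency(adjacency)
  if (sum(adjacency) / 2 < 2)
    stopf("need at least 2 edges")
  cp_real <- mean(cpp_clustering(adjacency))
  lp_real <- cpp_path_metrics(adjacency)$lp
  nulls <- cpp_null_metrics(adjacency, config$n_random,
                            config$swaps_per_edge, config$seed)
  cp_rand <- mean(nulls[, "cp"])
  lp_rand <- mean(nulls[, "lp"], na.rm = TRUE)
  if (is.na(cp_rand) || cp_rand == 0) {
    warning("null mean clustering is zero; gamma undefined", call. = FALSE)
    gam <- NA_real_
  } else gam <- cp_real / cp_rand
  lam <- if (is.na(lp_rand) || lp_rand == 0) NA_real_ else lp_real / lp_rand
  list(gamma = gam, lambda_norm = lam,
       sigma = if (is.na(gam) || is.na(lam)) NA_real_ else gam / lam,
       cp_real = cp_real, lp_real = lp_real,
       cp_rand = cp_rand, lp_rand = lp_rand)
}

#' AUC over the sparsity grid
#'
#' Trapezoidal integral of a per-threshold metric over the sparsity values,
#' the standard threshold-independent summary of a metric curve.
#'
#' @param values Metric values, one per threshold (finite).
#' @param grid A [sparsity_grid()] (or numeric vector of thresholds).
#' @return The trapezoidal AUC.
#' @export
auc_over_sparsity <- function(values, grid = sparsity_grid()) {
  s <- if (inherits(grid, "sparsity_grid")) grid$thresholds else grid
  if (length(s) < 2) stopf("need at least 2 thresholds for an AUC")
  if (length(values) != length(s))
    stopf("values (%d) and thresholds (%d) differ in length",
          length(values), length(s))
  if (any(!is.finite(values))) stopf("metric values must be finite")
  sum(diff(s) * (head(values, -1) + tail(values, -1)) / 2)
}

#' Compute all topology metrics for a thresholded graph stack
#'
#' At every sparsity threshold: clustering coefficient Cp, characteristic
#' path length Lp, global efficiency Eglob, local efficiency Eloc, nodal
#' efficiency Enod per node, and (when `null_config` is supplied) gamma,
#' lambda and sigma against degree-preserving random networks, each null
#' ensemble consuming a substream seeded by (config seed, threshold index).
#' Every global metric and every node's Enod curve is summarized by its
#' trapezoidal AUC over the grid.
#'
#' @param stack A [binarize_stack()] result.
#' @param grid The [sparsity_grid()] used to build the stack.
#' @param null_config A [null_model_config()], or `NULL` to skip the
#'   random-network normalization (gamma/lambda/sigma reported as `NA`).
#' @return Object of class `metric_curves`: `subject_id`, `thresholds`,
#'   `global` (data.frame threshold x metric), `auc_global` (named vector),
#'   `nodal` (threshold x node Enod matrix), `auc_nodal` (per-node vector).
#' @export
compute_all_metrics <- function(stack, grid = sparsity_grid(),
                                null_config = null_model_config()) {
  if (!isTRUE(all.equal(stack$thresholds, grid$thresholds)))
    stopf("stack thresholds do not match the grid")
  s <- stack$thresholds
  nt <- length(s)
  n <- nrow(stack$adjacency[[1]])
  glob <- data.frame(threshold = s, cp = NA_real_, lp = NA_real_,
                     eglob = NA_real_, eloc = NA_real_, gamma = NA_real_,
                     lambda = NA_real_, sigma = NA_real_)
  nodal <- matrix(NA_real_, nt, n)
  any_disconnected <- FALSE
  for (t in seq_len(nt)) {
    A <- stack$adjacency[[t]]
    storage.mode(A) <- "integer"
    glob$cp[t] <- mean(cpp_clustering(A))
    pm <- cpp_path_metrics(A)
    if (pm$unreached_pairs > 0) any_disconnected <- TRUE
    glob$lp[t] <- pm$lp
    glob$eglob[t] <- pm$eglob
    nodal[t, ] <- pm$enod
    glob$eloc[t] <- mean(cpp_local_efficiency(A))
    if (!is.null(null_config)) {
      nulls <- cpp_null_metrics(A, null_config$n_random,
                                null_config$swaps_per_edge,
                                substream_seed(null_config$seed, 0L, t))
      cp_rand <- mean(nulls[, "cp"])
      lp_rand <- mean(nulls[, "lp"], na.rm = TRUE)
      glob$gamma[t] <- if (cp_rand > 0) glob$cp[t] / cp_rand else NA_real_
      glob$lambda[t] <- if (!is.na(lp_rand) && lp_rand > 0)
        glob$lp[t] / lp_rand else NA_real_
      glob$sigma[t] <- glob$gamma[t] / glob$lambda[t]
    }
  }
  if (any_disconnected)
    warning(sprintf("subject %s: disconnected pairs excluded from Lp at some thresholds",
                    stack$subject_id), call. = FALSE)
  metric_names <- c("cp", "lp", "eglob", "eloc", "gamma", "lambda", "sigma")
  auc_global <- vapply(metric_names, function(m) {
    v <- glob[[m]]
    if (any(!is.finite(v))) NA_real_ else auc_over_sparsity(v, grid)
  }, numeric(1))
  auc_nodal <- apply(nodal, 2, auc_over_sparsity, grid = grid)
  structure(list(subject_id = stack$subject_id, thresholds = s,
                 global = glob, auc_global = auc_global,
                 nodal = nodal, auc_nodal = auc_nodal),
            class = "metric_curves")
}
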