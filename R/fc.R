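#' Pearson functional-connectivity matrix
#'
#' Correlates every pair of ROI columns. The result is symmetric with a unit
#' diagonal and entries clamped to [-1, 1].
#'
#' @param series A [roi_time_series()] with at least 3 time points and no
#'   constant columns.
#' @return Object of class `fc_matrix` with fields `subject_id` and `r`
#'   (N x N correlation matrix, dimnames = node ids when available).
#' @export
compute_fc <- function(series) {
  x <- series$data
  if (nrow(x) < 3) stopf("need at least 3 time points to correlate")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- bad
    stopf("constant (zero-variance) column(s): node %s",
          paste(nm, collapse = ", "))
  }
  r <- cor(x)
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  structure(list(subject_id = series$subject_id, r = r), class = "fc_matrix")
}

#' Sparsity grid
#'
#' Ordered sparsity thresholds from `s_min` to `s_max` in steps of `step`
#' (defaults: 0.10 to 0.34 step 0.01, i.e. 25 thresholds). The span must be
#' an integral number of steps.
#'
#' @param s_min,s_max,step Fractions in (0, 1).
#' @return Object of class `sparsity_grid` with field `thresholds`.
#' @export
sparsity_grid <- function(s_min = 0.10, s_max = 0.34, step = 0.01) {
  if (!(s_min > 0 && s_min < s_max && s_max < 1))
    stopf("need 0 < s_min < s_max < 1")
  k <- (s_max - s_min) / step
  if (abs(k - round(k)) > 1e-9)
    stopf("(s_max - s_min) must be an integral multiple of step")
  structure(list(s_min = s_min, s_max = s_max, step = step,
                 thresholds = s_min + step * (0:round(k))),
            class = "sparsity_grid")
}

# edges retained at sparsity s on n nodes (round half away from zero)
sparsity_edge_count <- function(s, n) {
  as.integer(round_half_away(s * n * (n - 1) / 2))
}

#' Binarize an FC matrix over a sparsity grid
#'
#' For each sparsity `s`, keeps exactly `round(s * N(N-1)/2)` node pairs with
#' the largest edge values and sets them to 1. Edge values are the signed
#' correlations by default (`edge_rank = "signed"`) or their absolute values
#' (`"absolute"`). Ties are broken by upper-triangle (row, column) order, so
#' the stack is deterministic; because a single edge ranking is used for all
#' thresholds, the stack is nested (every edge present at sparsity `s` is
#' present at every larger sparsity).
#'
#' @param fc An [compute_fc()] result.
#' @param grid A [sparsity_grid()].
#' @param edge_rank `"signed"` (default) or `"absolute"`.
#' @return Object of class `graph_stack`: fields `subject_id`, `thresholds`,
#'   and `adjacency` (list of binary integer matrices).
#' @export
binarize_stack <- function(fc, grid = sparsity_grid(),
                           edge_rank = c("signed", "absolute")) {
  edge_rank <- match.arg(edge_rank)
  r <- fc$r
  n <- nrow(r)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs < 1 / grid$step)
    stopf("too few node pairs (%d) for grid step %g", n_pairs, grid$step)
  ut <- which(upper.tri(r))
  i_idx <- row(r)[ut]
  j_idx <- col(r)[ut]
  v <- r[ut]
  if (edge_rank == "absolute") v <- abs(v)
  ord <- order(-v, i_idx, j_idx)
  counts <- sparsity_edge_count(grid$thresholds, n)
  if (max(counts) > n_pairs)
    stopf("requested edge count %d exceeds available pairs %d",
          max(counts), n_pairs)
  adj <- vector("list", length(counts))
  A <- matrix(0L, n, n)
  prev <- 0L
  for (t in seq_along(counts)) {
    m <- counts[t]
    if (m > prev) {
      sel <- ord[(prev + 1L):m]
      A[cbind(i_idx[sel], j_idx[sel])] <- 1L
      A[cbind(j_idx[sel], i_idx[sel])] <- 1L
      prev <- m
    }
    adj[[t]] <- A
  }
  structure(list(subject_id = fc$subject_id, thresholds = grid$thresholds,
                 adjacency = adj),
            class = "graph_stack")
}
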