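#' ROI time-series container
#'
#' A single subject's T x N matrix of BOLD-like signal, with subject id,
#' group label and repetition time.
#'
#' @param data Numeric T x N matrix (rows = time points, columns = nodes).
#' @param subject_id Subject identifier.
#' @param group `"patient"` or `"control"` (other labels allowed).
#' @param tr_seconds Repetition time in seconds.
#' @return An object of class `roi_ts`.
#' @export
roi_time_series <- function(data, subject_id, group, tr_seconds = 2) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("data must be a numeric matrix")
  if (anyNA(data)) stopf("data must not contain missing values")
  if (nrow(data) < 3) stopf("data must have at least 3 time points")
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group),
                 data = data, tr_seconds = tr_seconds),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s (%s): %d time points x %d nodes, TR = %gs\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Specify a synthetic two-group cohort
#'
#' Defines the generative model for a patient/control ROI time-series cohort:
#' a base graph topology (Watts-Strogatz small-world by default) inducing a
#' neighbourhood-overlap correlation structure, AR(1) temporal smoothing,
#' additive white noise, a multiplicative attenuation of patients'
#' within-neighbourhood correlations (emulating reduced local
#' interconnectivity), and optional node-specific connectivity shifts at
#' designated discriminative nodes.
#'
#' Defaults emulate a 20 + 20 cohort scanned at TR = 2 s with 200 acquired
#' volumes of which the first 10 are discarded downstream.
#'
#' @param n_per_group Subjects per group.
#' @param n_nodes Number of atlas nodes.
#' @param n_timepoints_raw Acquired time points per subject.
#' @param n_discard Initial volumes the preprocessing will discard (kept here
#'   so specs document the retained length; the generator emits raw length).
#' @param tr_seconds Repetition time (s).
#' @param base_topology `"small_world"`, `"modular"` or `"random"`.
#' @param ws_k Even lattice degree of the Watts-Strogatz base (also sets the
#'   edge count of the `"random"` base).
#' @param ws_rewire Watts-Strogatz rewiring probability.
#' @param n_modules Number of modules for the `"modular"` base.
#' @param within_module_weight Weight of the graph-local (neighbourhood
#'   overlap / within-module) correlation component, in [0, 1].
#' @param between_module_weight Weight of the global background correlation.
#' @param patient_local_attenuation Multiplicative factor in (0, 1] applied
#'   to patients' within-neighbourhood correlations.
#' @param discriminative_nodes `NULL` or a data.frame with columns `node_id`
#'   and `effect` (signed correlation-scale shift applied to that node's
#'   off-diagonal row/column in the patient group).
#' @param ar1_coefficient AR(1) coefficient in [0, 1).
#' @param noise_sd SD of additive white measurement noise (signal units;
#'   the latent signal is unit-variance).
#' @param seed Master integer seed; per-subject draws use derived substreams.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20, n_nodes = 160,
                        n_timepoints_raw = 200, n_discard = 10,
                        tr_seconds = 2, base_topology = "small_world",
                        ws_k = 12, ws_rewire = 0.1, n_modules = 6,
                        within_module_weight = 0.5,
                        between_module_weight = 0.05,
                        patient_local_attenuation = 0.8,
                        discriminative_nodes = NULL,
                        ar1_coefficient = 0.4, noise_sd = 0.2, seed = 1) {
  base_topology <- match.arg(base_topology, c("small_world", "modular", "random"))
  if (!is_count(n_per_group) || n_per_group < 1) stopf("n_per_group must be >= 1")
  if (!is_count(n_nodes) || n_nodes < 4) stopf("n_nodes must be >= 4")
  if (!is_count(n_timepoints_raw)) stopf("n_timepoints_raw must be a count")
  if (!is_count(n_discard) || n_discard >= n_timepoints_raw)
    stopf("n_discard must be a count smaller than n_timepoints_raw")
  if (within_module_weight < 0 || between_module_weight < 0 ||
      within_module_weight + between_module_weight > 1)
    stopf("within/between weights must be non-negative with sum <= 1")
  if (patient_local_attenuation <= 0 || patient_local_attenuation > 1)
    stopf("patient_local_attenuation must be in (0, 1]")
  if (ar1_coefficient < 0 || ar1_coefficient >= 1)
    stopf("ar1_coefficient must be in [0, 1)")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (ws_k %% 2 != 0 || ws_k < 2) stopf("ws_k must be a positive even count")
  if (!is.null(discriminative_nodes)) {
    if (!is.data.frame(discriminative_nodes) ||
        !all(c("node_id", "effect") %in% names(discriminative_nodes)))
      stopf("discriminative_nodes must be a data.frame with node_id and effect")
    if (any(discriminative_nodes$node_id < 1 |
            discriminative_nodes$node_id > n_nodes))
      stopf("discriminative node_ids must lie within 1..n_nodes")
  }
  structure(list(n_per_group = n_per_group, n_nodes = n_nodes,
                 n_timepoints_raw = n_timepoints_raw, n_discard = n_discard,
                 tr_seconds = tr_seconds, base_topology = base_topology,
                 ws_k = ws_k, ws_rewire = ws_rewire, n_modules = n_modules,
                 within_module_weight = within_module_weight,
                 between_module_weight = between_module_weight,
                 patient_local_attenuation = patient_local_attenuation,
                 discriminative_nodes = discriminative_nodes,
                 ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Discriminative-node effects matching the shipped reference model
#'
#' Returns a `discriminative_nodes` table for [cohort_spec()] covering the
#' nine anchor nodes of the packaged reference classifier, with shift signs
#' taken from the sign of each node's reference coefficient (positive for
#' nodes whose efficiency is elevated in patients).
#'
#' @param magnitude Absolute correlation-scale shift per node. The default
#'   0.04 produces roughly a one-SD shift in nodal-efficiency AUC at the
#'   affected nodes under the default cohort spec when preprocessing omits
#'   global-signal regression (GSR absorbs much of a uniform row shift).
#' @param node_ids Optional subset of the nine anchor node ids.
#' @return data.frame with columns `node_id`, `effect`.
#' @export
reference_effects <- function(magnitude = 0.04, node_ids = NULL) {
  anchors <- atlas_anchor_nodes()
  sign_up <- c(`21` = 1, `30` = 1, `117` = 1, `126` = 1, `143` = 1,
               `150` = 1, `42` = -1, `62` = -1, `98` = -1)
  eff <- data.frame(node_id = as.integer(names(sign_up)),
                    effect = unname(sign_up) * magnitude)
  eff <- eff[order(eff$node_id), , drop = FALSE]
  rownames(eff) <- NULL
  if (!is.null(node_ids)) {
    if (!all(node_ids %in% eff$node_id))
      stopf("node_ids must be among the anchor nodes %s",
            paste(eff$node_id, collapse = ", "))
    eff <- eff[match(node_ids, eff$node_id), , drop = FALSE]
    rownames(eff) <- NULL
  }
  stopifnot(all(eff$node_id %in% anchors$node_id))
  eff
}

# Base graph adjacency for a cohort spec (deterministic given spec$seed).
base_graph_adjacency <- function(spec) {
  n <- spec$n_nodes
  with_local_seed(substream_seed(spec$seed, 999L), {
    if (spec$base_topology == "small_world") {
      g <- igraph::sample_smallworld(1, n, spec$ws_k / 2, spec$ws_rewire)
    } else if (spec$base_topology == "random") {
      g <- igraph::sample_gnm(n, n * spec$ws_k / 2)
    } else {
      membership <- rep(seq_len(spec$n_modules), length.out = n)
      A <- outer(membership, membership, "==") * 1L
      diag(A) <- 0L
      return(A)
    }
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    A[A > 1] <- 1L
    diag(A) <- 0L
    storage.mode(A) <- "integer"
    A
  })
}

#' Ground-truth correlation matrix for one group
#'
#' Builds the N x N positive-definite correlation matrix underlying the
#' simulated BOLD signal. The control matrix is
#' `C = w * C0 + b * J + (1 - w - b) * I`, where `C0` is the row-normalized
#' neighbourhood-overlap matrix `(A + I)(A + I)'` of the base graph (a block
#' indicator for the modular topology), `J` the all-ones background and
#' `w`, `b` the within/between weights — a sum of PSD parts, so positive
#' definite whenever `w + b < 1`. The patient matrix multiplies
#' within-neighbourhood entries by `patient_local_attenuation`, adds the
#' signed `discriminative_nodes` shifts to those nodes' off-diagonal rows/columns,
#' and, if the result loses positive definiteness, applies diagonal loading
#' `(|min eigenvalue| + 0.01) * I` followed by renormalization to
#' correlation form.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"patient"`.
#' @return N x N correlation matrix with unit diagonal.
#' @export
build_ground_truth_covariance <- function(spec, group = c("control", "patient")) {
  group <- match.arg(group)
  n <- spec$n_nodes
  A <- base_graph_adjacency(spec)
  w <- spec$within_module_weight
  b <- spec$between_module_weight
  if (spec$base_topology == "modular") {
    C0 <- A + diag(n)  # block indicator incl. diagonal
  } else {
    M <- A + diag(n)
    rn <- sqrt(rowSums(M))
    C0 <- (M %*% t(M)) / outer(rn, rn)
  }
  C <- w * C0 + b + (1 - w - b) * diag(n)
  # neighbourhood mask: base-graph edges (within-module pairs when modular)
  mask <- A == 1
  if (group == "patient") {
    modified <- FALSE
    att <- spec$patient_local_attenuation
    if (att < 1) {
      C[mask] <- C[mask] * att
      modified <- TRUE
    }
    dn <- spec$discriminative_nodes
    if (!is.null(dn) && nrow(dn)) {
      for (r in seq_len(nrow(dn))) {
        v <- dn$node_id[r]
        C[v, -v] <- C[v, -v] + dn$effect[r]
        C[-v, v] <- C[v, -v]
      }
      modified <- TRUE
    }
    if (modified) {
      off <- row(C) != col(C)
      C[off] <- pmin(pmax(C[off], -0.99), 0.99)
      C <- (C + t(C)) / 2
      ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min <= 1e-10) {
        eps <- abs(ev_min) + 0.01
        C <- C + eps * diag(n)
        C <- stats::cov2cor(C)
      }
      ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min <= 0)
        stopf("internal error: covariance not positive definite after loading (min eigenvalue %g)", ev_min)
    }
  }
  dimnames(C) <- NULL
  C
}

#' Simulate a two-group ROI time-series cohort
#'
#' Draws, for each subject, `n_timepoints_raw` multivariate-normal
#' innovations from the group's ground-truth covariance, passes them through
#' a recursive AR(1) filter with the spec's coefficient, and adds white
#' measurement noise. A shared AR coefficient leaves the stationary
#' cross-correlation equal to the innovation correlation, so the empirical
#' FC of long simulations converges to the ground truth (attenuated by the
#' white-noise variance). Each subject consumes a substream derived from the
#' master seed, so output is bit-identical for a fixed seed and independent
#' of cohort-level reordering.
#'
#' @param spec A [cohort_spec()].
#' @param atlas Atlas table; must have `spec$n_nodes` rows.
#' @return List of `2 * n_per_group` [roi_time_series()] objects
#'   (controls first, then patients).
#' @export
simulate_cohort <- function(spec, atlas) {
  if (nrow(atlas) != spec$n_nodes)
    stopf("atlas has %d nodes but spec expects %d", nrow(atlas), spec$n_nodes)
  if (!is.null(spec$discriminative_nodes) &&
      !all(spec$discriminative_nodes$node_id %in% atlas$node_id))
    stopf("discriminative nodes must be atlas node_ids")
  groups <- c("control", "patient")
  chol_by_group <- lapply(groups, function(g)
    chol(build_ground_truth_covariance(spec, g)))
  names(chol_by_group) <- groups
  phi <- spec$ar1_coefficient
  t_raw <- spec$n_timepoints_raw
  n <- spec$n_nodes
  out <- vector("list", 2 * spec$n_per_group)
  idx <- 0L
  for (g in groups) {
    U <- chol_by_group[[g]]
    for (s in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("sub-%s-%03d", substr(g, 1, 3), s)
      x <- with_local_seed(substream_seed(spec$seed, idx), {
        innov <- matrix(rnorm(t_raw * n), t_raw, n) %*% U
        sig <- if (phi > 0)
          as.matrix(stats::filter(innov, phi, method = "recursive"))
        else innov
        if (spec$noise_sd > 0)
          sig <- sig + matrix(rnorm(t_raw * n, sd = spec$noise_sd), t_raw, n)
        sig
      })
      colnames(x) <- atlas$node_id
      out[[idx]] <- roi_time_series(x, sid, g, spec$tr_seconds)
    }
  }
  out
}
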