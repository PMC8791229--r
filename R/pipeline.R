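#' Read a cohort from a manifest
#'
#' The manifest is a CSV with columns `subject_id,group,path`; each path
#' (relative to the manifest's directory unless absolute) is a TSV whose
#' rows are time points and whose columns are nodes.
#'
#' @param manifest_path Manifest CSV path.
#' @param tr_seconds Repetition time attached to each series.
#' @return List of [roi_time_series()] objects.
#' @export
read_cohort <- function(manifest_path, tr_seconds = 2) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group", "path") %in% names(man)))
    stopf("manifest must have columns subject_id, group, path")
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p)) stopf("time-series file not found: %s", man$path[i])
    x <- as.matrix(read.delim(p, check.names = FALSE))
    roi_time_series(x, man$subject_id[i], man$group[i], tr_seconds)
  })
}

# preprocess -> FC -> binarize -> metrics for every subject; per-subject
# null substreams derived from (null seed, subject index).
cohort_metric_curves <- function(cohort, prep = prep_config(),
                                 grid = sparsity_grid(),
                                 null_config = null_model_config(),
                                 edge_rank = "signed") {
  lapply(seq_along(cohort), function(i) {
    series <- preprocess(cohort[[i]], prep)
    stack <- binarize_stack(compute_fc(series), grid, edge_rank)
    nc <- null_config
    if (!is.null(nc)) nc$seed <- substream_seed(null_config$seed, i)
    suppressWarnings(compute_all_metrics(stack, grid, nc))
  })
}

# long AUC table (global + nodal families) from per-subject metric curves
metrics_auc_table <- function(curves, cohort) {
  stopifnot(length(curves) == length(cohort))
  rows <- lapply(seq_along(curves), function(i) {
    mc <- curves[[i]]
    g <- mc$auc_global[!is.na(mc$auc_global)]
    rbind(
      data.frame(subject_id = mc$subject_id, group = cohort[[i]]$group,
                 family = "global", name = names(g), auc = unname(g),
                 stringsAsFactors = FALSE),
      data.frame(subject_id = mc$subject_id, group = cohort[[i]]$group,
                 family = "nodal", name = as.character(seq_along(mc$auc_nodal)),
                 auc = mc$auc_nodal, stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nodal-efficiency AUC feature matrix for classification
#'
#' Runs preprocessing, FC construction, sparsity binarization and nodal
#' efficiency (no random-network normalization, which Enod does not need)
#' for every subject and returns the subjects x nodes matrix of Enod AUC
#' values plus the group labels.
#'
#' @param cohort List of [roi_time_series()].
#' @param prep A [prep_config()].
#' @param grid A [sparsity_grid()].
#' @param edge_rank Edge-ranking rule for [binarize_stack()].
#' @return List with `features` (matrix, columns named by node id) and
#'   `labels` (character vector).
#' @export
enod_auc_features <- function(cohort, prep = prep_config(),
                              grid = sparsity_grid(),
                              edge_rank = "signed") {
  curves <- cohort_metric_curves(cohort, prep, grid, NULL, edge_rank)
  features <- do.call(rbind, lapply(curves, function(mc) mc$auc_nodal))
  colnames(features) <- as.character(seq_len(ncol(features)))
  rownames(features) <- vapply(cohort, function(s) s$subject_id, "")
  list(features = features,
       labels = vapply(cohort, function(s) s$group, ""))
}

#' Pipeline run configuration
#'
#' @param manifest Path to the cohort manifest CSV.
#' @param atlas Path to the atlas CSV.
#' @param output_dir Directory for result files (created if needed).
#' @param prep A [prep_config()] (its `gsr` flag is overridden per variant).
#' @param grid A [sparsity_grid()].
#' @param null_config A [null_model_config()].
#' @param n_folds CV folds for the classifier.
#' @param boot_n Bootstrap resamples for the ROC AUC CI.
#' @param seed Master seed; every stage consumes a derived substream.
#' @param variants Which GSR variants to run: subset of
#'   `c("gsr_on", "gsr_off")`.
#' @param tr_seconds Repetition time of the input series.
#' @param edge_rank Edge-ranking rule for binarization.
#' @return Object of class `run_config`.
#' @export
run_config <- function(manifest, atlas, output_dir,
                       prep = prep_config(), grid = sparsity_grid(),
                       null_config = null_model_config(), n_folds = 10,
                       boot_n = 2000, seed = 1,
                       variants = c("gsr_on", "gsr_off"),
                       tr_seconds = 2, edge_rank = "signed") {
  variants <- match.arg(variants, several.ok = TRUE)
  structure(list(manifest = manifest, atlas = atlas,
                 output_dir = output_dir, prep = prep, grid = grid,
                 null_config = null_config, n_folds = n_folds,
                 boot_n = boot_n, seed = as.integer(seed),
                 variants = variants, tr_seconds = tr_seconds,
                 edge_rank = edge_rank),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the arguments of [run_config()], with nested `prep`,
#' `grid` and `null_config` sections; relative paths are resolved against
#' the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  prep_args <- y$prep %||% list()
  grid_args <- y$grid %||% list()
  null_args <- y$null_config %||% list()
  run_config(manifest = resolve(y$manifest), atlas = resolve(y$atlas),
             output_dir = y$output_dir %||% file.path(base, "results"),
             prep = do.call(prep_config, prep_args),
             grid = do.call(sparsity_grid, grid_args),
             null_config = do.call(null_model_config, null_args),
             n_folds = y$n_folds %||% 10, boot_n = y$boot_n %||% 2000,
             seed = y$seed %||% 1,
             variants = y$variants %||% c("gsr_on", "gsr_off"),
             tr_seconds = y$tr_seconds %||% 2,
             edge_rank = y$edge_rank %||% "signed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full connectome-topology pipeline
#'
#' For each requested global-signal-regression variant: preprocess every
#' subject, build FC matrices, binarize over the sparsity grid, compute all
#' topology metrics with degree-preserving null normalization, compare
#' AUC-summarized metrics between groups (FDR over nodes), fit the LASSO
#' classifier on Enod AUC features, evaluate it with ROC/Youden, and (for
#' cohorts large enough) run the repeated-subsampling internal validation.
#' All result tables are written as CSV/JSON under
#' `output_dir/<variant>/` and a structured log records per-stage seeds.
#'
#' @param config A [run_config()] or the path to a YAML configuration.
#' @return Named list (one entry per variant) of reports, each with
#'   `metrics_auc` (long table), `group_comparison`, `classifier`,
#'   `roc`, `validation` and `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  atlas <- read_atlas(config$atlas)
  cohort <- read_cohort(config$manifest, config$tr_seconds)
  if (length(cohort) < 4) stopf("need at least 4 subjects")
  groups <- unique(vapply(cohort, function(s) s$group, ""))
  if (length(groups) != 2) stopf("manifest must contain exactly two groups")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run_log.txt")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  logf("pipeline start: %d subjects, %d nodes, seed %d",
       length(cohort), nrow(atlas), config$seed)
  reports <- list()
  for (variant in config$variants) {
    vdir <- file.path(config$output_dir, variant)
    dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
    prep <- config$prep
    prep$gsr <- identical(variant, "gsr_on")
    nc <- config$null_config
    nc$seed <- substream_seed(config$seed, match(variant, config$variants), 1L)
    logf("%s: metrics (null seed %d, %d nulls)", variant, nc$seed, nc$n_random)
    curves <- cohort_metric_curves(cohort, prep, config$grid, nc,
                                   config$edge_rank)
    auc_tab <- metrics_auc_table(curves, cohort)
    comparison <- compare_groups(auc_tab)
    feat <- enod_auc_features(cohort, prep, config$grid, config$edge_rank)
    cls_seed <- substream_seed(config$seed, match(variant, config$variants), 2L)
    logf("%s: classifier (seed %d, %d folds)", variant, cls_seed,
         config$n_folds)
    model <- fit_lasso_cv(feat$features, feat$labels,
                          n_folds = config$n_folds, seed = cls_seed)
    scores <- predict_probability(model, feat$features)
    roc <- roc_with_youden(scores, feat$labels, boot_n = config$boot_n,
                           seed = cls_seed)
    validation <- NULL
    if (nrow(feat$features) >= 39) {
      validation <- internal_validation(model, feat$features, feat$labels,
                                        seed = substream_seed(config$seed,
                                                              match(variant, config$variants), 3L))
    } else {
      logf("%s: cohort too small for the 21..39 internal validation; skipped",
           variant)
    }
    files <- c(
      metrics_auc = file.path(vdir, "metrics_auc.csv"),
      group_comparison = file.path(vdir, "group_comparison.csv"),
      classifier = file.path(vdir, "classifier.json"),
      roc_curve = file.path(vdir, "roc_curve.csv")
    )
    write.csv(auc_tab, files["metrics_auc"], row.names = FALSE)
    write.csv(comparison, files["group_comparison"], row.names = FALSE)
    jsonlite::write_json(
      list(penalty_lambda = model$penalty_lambda,
           intercept = model$intercept,
           coefficients = as.list(model$coefficients),
           selected_nodes = model$selected_nodes,
           cutoff = roc$cutoff, auc = roc$auc,
           ci = c(roc$ci_low, roc$ci_high),
           sensitivity = roc$sensitivity, specificity = roc$specificity),
      files["classifier"], auto_unbox = TRUE, digits = NA)
    write.csv(roc$curve, files["roc_curve"], row.names = FALSE)
    if (!is.null(validation)) {
      files["validation"] <- file.path(vdir, "validation.csv")
      write.csv(validation, files["validation"], row.names = FALSE)
    }
    logf("%s: done (ROC AUC %.3f, %d selected nodes)", variant, roc$auc,
         length(model$selected_nodes))
    reports[[variant]] <- list(metrics_auc = auc_tab,
                               group_comparison = comparison,
                               classifier = model, roc = roc,
                               validation = validation, files = files)
  }
  logf("pipeline complete")
  reports
}

#' Write a ready-to-run synthetic demo data set
#'
#' Generates the atlas, a two-group synthetic cohort (by default 20 + 20
#' subjects emulating the study design, with the nine reference
#' discriminative nodes active), the subject TSV files, the manifest and a
#' YAML pipeline configuration.
#'
#' @param seed Integer seed.
#' @param output_dir Writable directory (created if needed).
#' @param spec Optional [cohort_spec()] override (its seed is replaced by
#'   `seed`).
#' @return Path to the written YAML config, invisibly.
#' @export
generate_demo <- function(seed, output_dir,
                          spec = cohort_spec(discriminative_nodes = reference_effects())) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stopf("cannot create directory %s", output_dir)
  spec$seed <- as.integer(seed)
  atlas <- make_atlas_fixture(spec$n_nodes, seed = substream_seed(seed, 1L))
  cohort <- simulate_cohort(spec, atlas)
  write_atlas(atlas, file.path(output_dir, "atlas.csv"))
  dir.create(file.path(output_dir, "timeseries"), showWarnings = FALSE)
  man <- data.frame(subject_id = character(), group = character(),
                    path = character(), stringsAsFactors = FALSE)
  for (s in cohort) {
    rel <- file.path("timeseries", paste0(s$subject_id, ".tsv"))
    write.table(s$data, file.path(output_dir, rel), sep = "\t",
                row.names = FALSE, quote = FALSE)
    man <- rbind(man, data.frame(subject_id = s$subject_id, group = s$group,
                                 path = rel, stringsAsFactors = FALSE))
  }
  write.csv(man, file.path(output_dir, "manifest.csv"), row.names = FALSE)
  cfg <- list(manifest = "manifest.csv", atlas = "atlas.csv",
              output_dir = file.path(output_dir, "results"),
              prep = list(n_discard = spec$n_discard),
              grid = list(s_min = 0.10, s_max = 0.34, step = 0.01),
              null_config = list(n_random = 100, swaps_per_edge = 10,
                                 seed = substream_seed(seed, 2L)),
              n_folds = 10, boot_n = 2000, seed = as.integer(seed),
              variants = c("gsr_on", "gsr_off"),
              tr_seconds = spec$tr_seconds)
  cfg_path <- file.path(output_dir, "run.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
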