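#' Load the packaged reference classification model
#'
#' The package ships a published nine-node LASSO-logistic model
#' (`inst/extdata/bsp_reference_model.json`) that classifies blepharospasm
#' patients against healthy controls from nodal-efficiency AUC features,
#' together with the group-mean feature values at its nodes, its decision
#' cutoff and its reported ROC summary. The loaded object can be used with
#' [predict_probability()] like any fitted `lasso_classifier`, which makes
#' it a self-contained worked example: evaluating the model at the
#' patient-group mean feature vector yields a score above the cutoff, and
#' at the control-group means a score below it.
#'
#' @param path JSON file to load (defaults to the packaged fixture).
#' @return A `lasso_classifier` with additional fields `cutoff`, `nodes`
#'   (per-node metadata data.frame with group means/SDs), `patient_means`,
#'   `control_means` (named feature vectors) and `reported_roc`.
#' @export
load_reference_model <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bsp_reference_model.json",
                        package = "connectopo")
  spec <- jsonlite::fromJSON(path)
  nodes <- spec$nodes
  node_names <- as.character(nodes$node_id)
  beta <- nodes$coefficient
  names(beta) <- node_names
  pm <- nodes$patient_mean
  cm <- nodes$control_mean
  names(pm) <- names(cm) <- node_names
  structure(list(penalty_lambda = NA_real_, coefficients = beta,
                 intercept = spec$intercept, selected_nodes = node_names,
                 positive_class = "patient", cv = NULL,
                 cutoff = spec$cutoff, nodes = nodes,
                 patient_means = pm, control_means = cm,
                 reported_roc = spec$reported_roc),
            class = c("reference_model", "lasso_classifier"))
}
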