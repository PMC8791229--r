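#' Fit an L1-penalized (LASSO) logistic classifier with cross-validation
#'
#' Fits a LASSO logistic regression of group on nodal-efficiency AUC
#' features over a descending penalty path (via glmnet, features
#' standardized internally, coefficients reported on the original scale).
#' The penalty is selected as the strict minimizer of the cross-validated
#' binomial deviance over `n_folds` class-stratified folds, and the returned
#' model is the path fit at that penalty.
#'
#' @param features Numeric subjects x nodes matrix; column names identify
#'   nodes.
#' @param labels Group label per subject (exactly two classes, >= 2 subjects
#'   each). `"patient"` is taken as the positive class when present,
#'   otherwise the last sorted label.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param lambda_fixed Optional fixed penalty; skips cross-validation and
#'   fits at this value (used for degenerate/diagnostic fits).
#' @return Object of class `lasso_classifier`: `penalty_lambda`,
#'   `coefficients` (named, nonzero only), `intercept`, `selected_nodes`,
#'   `positive_class`, and (for CV fits) `cv` (data.frame `lambda`, `cvm`,
#'   `cvsd`).
#' @export
fit_lasso_cv <- function(features, labels, n_folds = 10, seed = 1,
                         lambda_fixed = NULL) {
  features <- as.matrix(features)
  if (anyNA(features)) stopf("features must not contain missing values")
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("node%d", seq_len(ncol(features)))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    stopf("labels must contain exactly two classes, found %d", length(classes))
  if (min(table(labels)) < 2) stopf("need at least 2 subjects per class")
  positive <- if ("patient" %in% classes) "patient" else classes[2]
  y <- as.integer(labels == positive)

  if (!is.null(lambda_fixed)) {
    fit <- glmnet::glmnet(features, y, family = "binomial",
                          lambda = lambda_fixed, standardize = TRUE)
    beta <- as.numeric(fit$beta[, 1])
    names(beta) <- rownames(fit$beta)
    intercept <- as.numeric(fit$a0[1])
    cv <- NULL
    lambda <- lambda_fixed
  } else {
    foldid <- integer(length(y))
    with_local_seed(substream_seed(seed, 17L), {
      for (cl in classes) {
        idx <- sample(which(labels == cl))
        foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    })
    cvfit <- glmnet::cv.glmnet(features, y, family = "binomial",
                               type.measure = "deviance", foldid = foldid,
                               standardize = TRUE)
    lambda <- cvfit$lambda.min
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
    intercept <- cf[1, 1]
    beta <- cf[-1, 1]
    cv <- data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                     cvsd = cvfit$cvsd)
  }
  nz <- beta[beta != 0]
  structure(list(penalty_lambda = lambda, coefficients = nz,
                 intercept = intercept, selected_nodes = names(nz),
                 positive_class = positive, cv = cv),
            class = "lasso_classifier")
}

#' @export
print.lasso_classifier <- function(x, ...) {
  cat(sprintf("<lasso_classifier> lambda = %.5g, %d selected node(s), intercept = %.4f\n",
              x$penalty_lambda, length(x$selected_nodes), x$intercept))
  invisible(x)
}

#' Predicted risk score of the logistic model
#'
#' `p = 1 / (1 + exp(-(intercept + sum_k coefficient_k * feature_k)))` over
#' the model's selected nodes.
#'
#' @param model A `lasso_classifier` (fitted or loaded).
#' @param features Named numeric vector for one subject, or a matrix /
#'   data.frame (rows = subjects) whose column names cover the selected
#'   nodes.
#' @param type `"response"` (probability, default) or `"link"` (linear
#'   predictor).
#' @return Numeric vector of scores.
#' @export
predict_probability <- function(model, features, type = c("response", "link")) {
  type <- match.arg(type)
  if (is.null(dim(features)))
    features <- matrix(features, 1, dimnames = list(NULL, names(features)))
  features <- as.matrix(features)
  missing_nodes <- setdiff(model$selected_nodes, colnames(features))
  if (length(missing_nodes))
    stopf("missing feature(s) for node(s): %s",
          paste(missing_nodes, collapse = ", "))
  x <- features[, model$selected_nodes, drop = FALSE]
  eta <- as.numeric(model$intercept + x %*% model$coefficients)
  if (type == "link") eta else plogis(eta)
}

# Tie-corrected rank-sum (Mann-Whitney) formulation of the ROC AUC.
auc_rank <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve with Youden-index cutoff
#'
#' Trapezoidal ROC AUC (equivalent to the tie-corrected rank statistic),
#' optimal decision cutoff maximizing Youden's index
#' (sensitivity + specificity - 1), sensitivity/specificity at that cutoff,
#' and a stratified-bootstrap percentile confidence interval for the AUC.
#'
#' @param scores Predicted risk scores.
#' @param labels Group labels (two classes).
#' @param positive Positive-class label (`"patient"` when present).
#' @param boot_n Bootstrap resamples for the AUC CI (default 2000).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `roc_summary`: `auc`, `ci_low`, `ci_high`,
#'   `sensitivity`, `specificity`, `cutoff`, `curve` (data.frame of
#'   threshold/sensitivity/specificity), `n_positive`, `n_negative`.
#' @export
roc_with_youden <- function(scores, labels, positive = NULL, boot_n = 2000,
                            seed = 1, conf_level = 0.95) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stopf("labels must contain exactly two classes")
  if (is.null(positive))
    positive <- if ("patient" %in% classes) "patient" else classes[2]
  negative <- setdiff(classes, positive)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]  # lowest threshold on Youden ties
  ci <- with_local_seed(substream_seed(seed, 23L),
                        pROC::ci.auc(r, conf.level = conf_level,
                                     method = "bootstrap", boot.n = boot_n,
                                     boot.stratified = TRUE))
  curve <- pROC::coords(r, "all",
                        ret = c("threshold", "sensitivity", "specificity"),
                        transpose = FALSE)
  structure(list(auc = auc, ci_low = as.numeric(ci[1]),
                 ci_high = as.numeric(ci[3]),
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 cutoff = best$threshold, curve = curve,
                 n_positive = sum(labels == positive),
                 n_negative = sum(labels == negative),
                 positive_class = positive),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> AUC = %.3f (%.3f-%.3f), sens = %.2f, spec = %.2f at cutoff %.4f\n",
              x$auc, x$ci_low, x$ci_high, x$sensitivity, x$specificity,
              x$cutoff))
  invisible(x)
}

#' Repeated-subsampling internal validation
#'
#' Draws `length(sizes)` testing sets from the whole cohort (default sizes
#' 21, 22, ..., 39) by simple random sampling without replacement (redrawn
#' when a draw contains a single class), scores each with the fixed model,
#' and records the ROC AUC per draw. Subsamples include training subjects,
#' so the resulting AUCs are optimistic by construction; they probe the
#' stability of the fitted model, not out-of-sample accuracy.
#'
#' @param model A `lasso_classifier`.
#' @param features Full-cohort feature matrix (rows = subjects).
#' @param labels Group labels aligned with `features`.
#' @param seed Integer seed (one substream per repeat).
#' @param sizes Strictly increasing subsample sizes (default `21:39`).
#' @return data.frame with `repeat_index`, `sample_size`, `auc`, `seed`.
#' @export
internal_validation <- function(model, features, labels, seed = 1,
                                sizes = 21:39) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) < max(sizes))
    stopf("cohort (%d) smaller than the largest subsample (%d)",
          nrow(features), max(sizes))
  positive <- model$positive_class
  scores_all <- predict_probability(model, features)
  out <- data.frame(repeat_index = seq_along(sizes), sample_size = sizes,
                    auc = NA_real_, seed = NA_integer_)
  for (r in seq_along(sizes)) {
    seed_r <- substream_seed(seed, r)
    out$seed[r] <- seed_r
    idx <- with_local_seed(seed_r, {
      for (attempt in 1:1000) {
        cand <- sample.int(nrow(features), sizes[r])
        if (length(unique(labels[cand])) == 2) break
      }
      cand
    })
    out$auc[r] <- auc_rank(scores_all[idx], labels[idx], positive)
  }
  out
}
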