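#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. The exact rank-sum
#' distribution is enumerated when both samples have at most 10 values and
#' no ties are present; otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param values_a,values_b Numeric samples (>= 2 values each).
#' @return List with `p_value`, `statistic` (rank-sum W of the first
#'   sample, Mann-Whitney form) and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stopf("each sample needs at least 2 values")
  if (anyNA(values_a) || anyNA(values_b)) stopf("samples must not contain NA")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !ties && length(values_a) <= 10 && length(values_b) <= 10
  ht <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  list(p_value = min(1, ht$p.value), statistic = unname(ht$statistic),
       method = if (exact) "exact" else "normal")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity; order-preserving.
#'
#' @param p_values Probabilities in [0, 1].
#' @return q-values of the same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Group comparison of AUC-summarized metrics
#'
#' Compares each metric's (or node's) per-subject AUC between the two groups
#' with the Wilcoxon rank-sum test. FDR (Benjamini-Hochberg) correction is
#' applied within the nodal family only; global metrics are reported with
#' raw p-values.
#'
#' @param auc_table Long data.frame with columns `subject_id`, `group`,
#'   `family` (`"global"` or `"nodal"`), `name` and `auc`.
#' @param groups Length-2 character vector naming (group A, group B); by
#'   default `c("patient", "control")` when those labels are present,
#'   otherwise the sorted unique labels.
#' @return data.frame with one row per metric/node: `family`,
#'   `metric_or_node`, group means and SDs, `p_value` and `q_value`
#'   (`NA` for the global family).
#' @export
compare_groups <- function(auc_table, groups = NULL) {
  need <- c("subject_id", "group", "family", "name", "auc")
  if (!all(need %in% names(auc_table)))
    stopf("auc_table must have columns %s", paste(need, collapse = ", "))
  labs <- unique(auc_table$group)
  if (length(labs) != 2) stopf("need exactly two groups, found %d", length(labs))
  if (is.null(groups)) {
    groups <- if (all(c("patient", "control") %in% labs))
      c("patient", "control") else sort(labs)
  }
  if (!all(groups %in% labs)) stopf("groups not found in auc_table")
  keys <- unique(auc_table[, c("family", "name")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- auc_table[auc_table$family == keys$family[i] &
                       auc_table$name == keys$name[i], ]
    a <- sub$auc[sub$group == groups[1]]
    b <- sub$auc[sub$group == groups[2]]
    w <- wilcoxon_rank_sum(a, b)
    data.frame(family = keys$family[i], metric_or_node = keys$name[i],
               group_a = groups[1], group_a_mean = mean(a), group_a_sd = sd(a),
               group_b = groups[2], group_b_mean = mean(b), group_b_sd = sd(b),
               p_value = w$p_value, q_value = NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  nodal <- res$family == "nodal"
  if (any(nodal)) res$q_value[nodal] <- fdr_adjust(res$p_value[nodal])
  rownames(res) <- NULL
  res
}
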