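test_that("predicted risk scores follow the logistic form", {
  m <- structure(list(coefficients = c(a = 0, b = 0), intercept = 0,
                      selected_nodes = c("a", "b"), positive_class = "patient"),
                 class = "lasso_classifier")
  expect_equal(predict_probability(m, c(a = 3, b = -1)), 0.5)
  m$coefficients <- c(a = 2, b = -1)
  m$intercept <- 0.5
  eta <- 0.5 + 2 * 0.3 - 1 * 0.2
  expect_equal(predict_probability(m, c(a = 0.3, b = 0.2)), plogis(eta))
  expect_equal(predict_probability(m, c(a = 0.3, b = 0.2), type = "link"), eta)
  expect_error(predict_probability(m, c(a = 1)), "missing feature.*b")
})

test_that("the packaged reference model reproduces its printed worked example", {
  ref <- load_reference_model()
  expect_length(ref$coefficients, 9)
  # frozen values computed by direct arithmetic over the printed
  # coefficient x group-mean products
  eta_pat <- sum(ref$coefficients * ref$patient_means) + ref$intercept
  expect_equal(eta_pat, 0.64567, tolerance = 1e-4)
  expect_equal(predict_probability(ref, ref$patient_means),
               plogis(eta_pat))
  expect_equal(predict_probability(ref, ref$patient_means), 0.65603,
               tolerance = 1e-4)
  eta_hc <- sum(ref$coefficients * ref$control_means) + ref$intercept
  expect_equal(eta_hc, -0.65124, tolerance = 1e-4)
  expect_equal(predict_probability(ref, ref$control_means), 0.34274,
               tolerance = 1e-4)
  # the patient mean vector scores above the shipped cutoff, the control
  # mean vector below it
  expect_gte(predict_probability(ref, ref$patient_means), ref$cutoff)
  expect_lte(predict_probability(ref, ref$control_means), ref$cutoff)
})

test_that("penalty extremes give full shrinkage and the unpenalized fit", {
  set.seed(21)
  n <- 40
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, sprintf("n%d", 1:6)))
  y <- rep(c("patient", "control"), each = n / 2)
  x[y == "patient", 1] <- x[y == "patient", 1] + 2
  big <- fit_lasso_cv(x, y, lambda_fixed = 50)
  expect_length(big$selected_nodes, 0)
  expect_equal(predict_probability(big, x[1, ]), plogis(big$intercept))

  # near-zero penalty on a separable 2-feature problem matches the
  # unpenalized logistic oracle in sign of the linear predictor
  x2 <- x[, 1:2]
  tiny <- fit_lasso_cv(x2, y, lambda_fixed = 1e-6)
  eta_lasso <- predict_probability(tiny, x2, type = "link")
  glm_fit <- suppressWarnings(glm((y == "patient") ~ x2, family = binomial))
  eta_glm <- as.numeric(cbind(1, x2) %*% coef(glm_fit))
  expect_true(all(sign(eta_lasso) == sign(eta_glm)))
})

test_that("cross-validated LASSO recovers strongly separated features", {
  hits <- logical(10)
  for (r in 1:10) {
    set.seed(500 + r)
    n <- 40; p <- 160
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, seq_len(p)))
    y <- rep(c("patient", "control"), each = 20)
    x[y == "patient", 7] <- x[y == "patient", 7] + 2
    x[y == "patient", 31] <- x[y == "patient", 31] - 2
    fit <- fit_lasso_cv(x, y, seed = r)
    hits[r] <- all(c("7", "31") %in% fit$selected_nodes)
  }
  expect_gte(mean(hits), 0.9)
})

test_that("the CV-selected penalty attains the minimal CV error on the path", {
  set.seed(33)
  x <- matrix(rnorm(50 * 20), 50, 20, dimnames = list(NULL, seq_len(20)))
  y <- rep(c("patient", "control"), 25)
  x[y == "patient", 3] <- x[y == "patient", 3] + 1.5
  fit <- fit_lasso_cv(x, y, seed = 2)
  expect_true(fit$penalty_lambda %in% fit$cv$lambda)
  expect_equal(fit$cv$cvm[fit$cv$lambda == fit$penalty_lambda],
               min(fit$cv$cvm))
})

test_that("ROC summaries match exhaustive pair counting and bound Youden cutoffs", {
  perfect <- suppressWarnings(
    roc_with_youden(c(0.9, 0.8, 0.1, 0.2), c("patient", "patient",
                                             "control", "control"),
                    boot_n = 50, seed = 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  scores <- c(0.1, 0.4, 0.35, 0.8)
  labs <- c("control", "patient", "control", "patient")
  r <- suppressWarnings(roc_with_youden(scores, labs, boot_n = 50, seed = 1))
  expect_equal(r$auc, oracle_auc_pairs(scores, labs, "patient"))
  expect_equal(r$auc, 1)  # all four patient x control pairs concordant
  expect_true(r$cutoff > 0.35 && r$cutoff <= 0.4)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)

  # a discordant labelling gives AUC 3/4 by the same pair enumeration
  labs2 <- c("control", "control", "patient", "patient")
  r2 <- roc_with_youden(scores, labs2, boot_n = 50, seed = 1)
  expect_equal(oracle_auc_pairs(scores, labs2, "patient"), 0.75)
  expect_equal(r2$auc, 0.75)
})

test_that("ROC AUC equals the tie-corrected rank-sum formulation", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    scores <- sample(round(runif(n), 2))  # induces ties
    labs <- sample(c("patient", "control"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    r <- pROC::roc(labs, scores, levels = c("control", "patient"),
                   direction = "<", quiet = TRUE)
    expect_lt(abs(as.numeric(pROC::auc(r)) -
                    connectopo:::auc_rank(scores, labs, "patient")), 1e-12)
  }
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(14)
  scores <- runif(200)
  near_half <- sapply(1:100, function(i) {
    labs <- sample(rep(c("patient", "control"), 100))
    abs(connectopo:::auc_rank(scores, labs, "patient") - 0.5) < 0.1
  })
  expect_gte(mean(near_half), 0.95)
})

test_that("internal validation draws the documented subsample ladder", {
  set.seed(8)
  n <- 40
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, 1:4))
  y <- rep(c("patient", "control"), each = 20)
  x[y == "patient", 2] <- x[y == "patient", 2] + 5  # near-perfect separator
  model <- fit_lasso_cv(x, y, lambda_fixed = 0.01)
  val <- internal_validation(model, x, y, seed = 3)
  expect_equal(val$sample_size, 21:39)
  expect_equal(val$repeat_index, 1:19)
  expect_true(all(val$auc > 0.9))
  val2 <- internal_validation(model, x, y, seed = 3)
  expect_identical(val, val2)
  expect_error(internal_validation(model, x[1:30, ], y[1:30], seed = 1),
               "smaller")
})
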