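test_that("atlas fixture has the documented structure and anchors", {
  atlas <- make_atlas_fixture(160, seed = 1)
  expect_equal(nrow(atlas), 160)
  expect_equal(atlas$node_id, 1:160)
  expect_true(all(table(atlas$network) > 0))
  # anchor regions at their fixed ids
  expect_equal(atlas$label[21], "Precuneus")
  expect_equal(atlas$hemisphere[21], "R")
  expect_equal(atlas$network[21], "Default")
  expect_equal(atlas$label[150], "Med cerebellum")
  expect_equal(atlas$network[150], "Cerebellum")
  # network proportions respected (within rounding of anchors)
  counts <- table(atlas$network)
  expect_equal(sort(names(counts)), sort(names(default_network_proportions())))
  expect_true(max(abs(counts / 160 - default_network_proportions()[names(counts)])) < 0.02)
})

test_that("atlas generation is deterministic and handles degenerate proportions", {
  a1 <- make_atlas_fixture(160, seed = 3)
  a2 <- make_atlas_fixture(160, seed = 3)
  expect_identical(a1, a2)
  one <- make_atlas_fixture(6, network_proportions = c(limbic = 1), seed = 1)
  expect_equal(nrow(one), 6)
  expect_true(all(one$network == "limbic"))
  expect_error(make_atlas_fixture(10, network_proportions = c(a = 0.6, b = 0.6)),
               "sum to 1")
})

test_that("ground-truth covariance honours null effects and degenerate weights", {
  spec <- cohort_spec(n_nodes = 40, ws_k = 6, patient_local_attenuation = 1,
                      seed = 5)
  expect_identical(build_ground_truth_covariance(spec, "control"),
                   build_ground_truth_covariance(spec, "patient"))
  spec0 <- cohort_spec(n_nodes = 20, ws_k = 4, within_module_weight = 0,
                       between_module_weight = 0, seed = 2)
  expect_equal(build_ground_truth_covariance(spec0, "control"), diag(20))
})

test_that("patient attenuation lowers within-neighbourhood correlations elementwise", {
  spec <- cohort_spec(n_nodes = 60, ws_k = 8, ws_rewire = 0.1,
                      patient_local_attenuation = 0.8, seed = 7)
  A <- connectopo:::base_graph_adjacency(spec)
  Cc <- build_ground_truth_covariance(spec, "control")
  Cp <- build_ground_truth_covariance(spec, "patient")
  edges <- A == 1
  expect_true(all(Cp[edges] < Cc[edges]))
  expect_lt(mean(Cp[edges]), mean(Cc[edges]))
  # both remain valid correlation matrices
  expect_equal(diag(Cp), rep(1, 60))
  expect_gt(min(eigen(Cp, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("simulated cohorts have the specified design and are reproducible", {
  spec <- cohort_spec(n_per_group = 3, n_nodes = 20, ws_k = 4,
                      n_timepoints_raw = 50, n_discard = 10, seed = 11)
  atlas <- make_atlas_fixture(20, seed = 1)
  cohort <- simulate_cohort(spec, atlas)
  expect_length(cohort, 6)
  expect_equal(sum(sapply(cohort, `[[`, "group") == "patient"), 3)
  expect_true(all(sapply(cohort, function(s) nrow(s$data)) == 50))
  kept <- discard_and_detrend(cohort[[1]], prep_config(n_discard = 10))
  expect_equal(nrow(kept$data), 40)
  cohort2 <- simulate_cohort(spec, atlas)
  expect_identical(cohort[[4]]$data, cohort2[[4]]$data)
})

test_that("independent-noise simulation decorrelates as T grows", {
  spec <- cohort_spec(n_per_group = 1, n_nodes = 20, ws_k = 4,
                      n_timepoints_raw = 5000, n_discard = 10,
                      within_module_weight = 0, between_module_weight = 0,
                      ar1_coefficient = 0, noise_sd = 1, seed = 4)
  atlas <- make_atlas_fixture(20, seed = 1)
  x <- simulate_cohort(spec, atlas)[[1]]$data
  r <- cor(x)
  off <- abs(r[upper.tri(r)])
  expect_gte(mean(off < 0.1), 0.95)
})

test_that("empirical correlation of long simulations converges to ground truth", {
  spec <- cohort_spec(n_per_group = 1, n_nodes = 60, ws_k = 8,
                      n_timepoints_raw = 20000, n_discard = 10,
                      noise_sd = 0, seed = 21)
  atlas <- make_atlas_fixture(60, seed = 1)
  x <- simulate_cohort(spec, atlas)[[1]]$data
  C <- build_ground_truth_covariance(spec, "control")
  expect_lt(max(abs(cor(x) - C)), 0.05)
})

test_that("cohort specs reject inconsistent settings", {
  expect_error(cohort_spec(n_discard = 200, n_timepoints_raw = 200), "n_discard")
  expect_error(cohort_spec(patient_local_attenuation = 0), "attenuation")
  expect_error(cohort_spec(discriminative_nodes = data.frame(node_id = 999, effect = 0.1)),
               "node_ids")
  spec <- cohort_spec(n_nodes = 30, ws_k = 4)
  expect_error(simulate_cohort(spec, make_atlas_fixture(20, seed = 1)), "atlas")
})
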