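test_that("largest-remainder quotas preserve class proportions", {
  labels <- rep(c("a", "b", "c"), c(60, 10, 30))
  idx <- stratified_sample_indices(labels, 10, seed = 1)
  expect_length(idx, 10)
  expect_equal(as.vector(table(factor(labels[idx], c("a", "b", "c")))),
               c(6, 1, 3))
  # quotas sum to size even when they do not divide evenly
  labels2 <- rep(c("a", "b", "c"), c(5, 5, 5))
  idx2 <- stratified_sample_indices(labels2, 7, seed = 3)
  expect_length(idx2, 7)
})

test_that("stratified draws are seeded and uniform within class", {
  labels <- rep("z", 10)
  i1 <- stratified_sample_indices(labels, 9, seed = 4)
  expect_length(i1, 9)
  expect_identical(i1, stratified_sample_indices(labels, 9, seed = 4))
  expect_false(identical(stratified_sample_indices(labels, 5, seed = 1),
                         stratified_sample_indices(labels, 5, seed = 2)))
  expect_error(stratified_sample_indices(labels, 10, seed = 1), "size < n")
})

test_that("run_trial is reproducible and reduces to a stratified draw", {
  dt <- tiny_two_class()
  cfg <- run_config(size = 4, seed = 10, n_trials = 5)
  tr <- run_trial(dt, cfg, 2)
  expect_identical(tr, run_trial(dt, cfg, 2))
  expect_equal(tr$trial_seed, 12L)
  expect_length(tr$per_variable_distance, 2)
  expect_equal(tr$max_distance, max(tr$per_variable_distance))
  expect_identical(tr$selected_indices,
                   stratified_sample_indices(dt$labels, 4, 12))
  expect_error(run_trial(dt, cfg, 6), "1..n_trials")
})

test_that("a single-trial run is plain stratified sampling", {
  dt <- tiny_two_class()
  cfg <- run_config(size = 4, seed = 3, n_trials = 1)
  res <- dp_downsample(dt, cfg)
  expect_identical(res$winner$selected_indices,
                   stratified_sample_indices(dt$labels, 4, 4))
  expect_equal(res$n_trials_run, 1L)
})

test_that("sample and removed partition the data with preserved priors", {
  withr::with_seed(5, dt <- data_table(matrix(rnorm(600), ncol = 3),
                                       labels = rep(c("A", "B"), c(150, 50))))
  res <- dp_downsample(dt, run_config(size = 40, seed = 0, n_trials = 30))
  expect_equal(nrow(res$sample$values) + nrow(res$removed$values), 200)
  expect_length(intersect(res$sample$row_ids, res$removed$row_ids), 0)
  expect_equal(as.vector(table(res$sample$labels)), c(30, 10))  # 3:1 priors
  expect_equal(res$winner$max_distance, min(res$trial_max_distances))
})

test_that("more trials never worsen the winner on prefix-nested schedules", {
  withr::with_seed(6, dt <- data_table(matrix(rnorm(400), ncol = 2),
                                       labels = rep(1:2, each = 100)))
  r10 <- dp_downsample(dt, run_config(size = 20, seed = 0, n_trials = 10))
  r100 <- dp_downsample(dt, run_config(size = 20, seed = 0, n_trials = 100))
  expect_equal(r100$trial_max_distances[1:10], r10$trial_max_distances)
  expect_lte(r100$winner$max_distance, r10$winner$max_distance)
})

test_that("result is independent of chunking and worker count", {
  withr::with_seed(8, dt <- data_table(matrix(rnorm(300), ncol = 3),
                                       labels = rep(1:2, each = 50)))
  base <- dp_downsample(dt, run_config(size = 12, seed = 2, n_trials = 40))
  chunked <- dp_downsample(dt, run_config(size = 12, seed = 2, n_trials = 40,
                                          job_size = 7))
  par2 <- dp_downsample(dt, run_config(size = 12, seed = 2, n_trials = 40,
                                       job_size = 7, max_workers = 2))
  expect_identical(base$winner, chunked$winner)
  expect_identical(base$winner, par2$winner)
  expect_equal(base$trial_max_distances, chunked$trial_max_distances)
})

test_that("ties in max distance resolve to the lowest trial seed", {
  # a constant variable gives every trial distance 0: all trials tie
  dt <- data_table(cbind(k = rep(2, 40)), labels = rep(1:2, each = 20))
  res <- dp_downsample(dt, run_config(size = 8, seed = 5, n_trials = 25,
                                      job_size = 6))
  expect_equal(res$winner$trial_seed, 6L)  # seed + 1
  expect_equal(res$winner$max_distance, 0)
})

test_that("the winner attains the exhaustive min-max optimum (ad)", {
  dt <- tiny_two_class()
  brute <- brute_force_minmax(dt, tiny_all_subsets(), "ad")
  res <- dp_downsample(dt, run_config(size = 4, seed = 0, n_trials = 600,
                                      metric_id = "ad"))
  expect_equal(res$winner$max_distance, brute, tolerance = 1e-12)
})

test_that("unlabelled data is sampled as a single class", {
  withr::with_seed(9, dt <- data_table(matrix(rnorm(100), ncol = 1)))
  res <- dp_downsample(dt, run_config(size = 10, seed = 0, n_trials = 5))
  expect_equal(nrow(res$sample$values), 10)
})

test_that("PCA importance keeps the dominant variable only", {
  withr::with_seed(10, {
    X <- cbind(sig = rnorm(300, sd = 10),
               matrix(rnorm(300 * 9, sd = 0.05), ncol = 9))
    colnames(X) <- c("sig", paste0("n", 1:9))
    dt <- data_table(X)
  })
  expect_identical(select_relevant_features_pca(dt), "sig")
  res <- dp_downsample(dt, run_config(size = 30, seed = 0, n_trials = 5,
                                      pca_importance = TRUE))
  expect_identical(res$variables_assessed, "sig")
})

test_that("PCA importance falls back gracefully on degenerate data", {
  dtc <- data_table(cbind(a = rep(1, 30), b = rep(2, 30)))
  expect_warning(sel <- select_relevant_features_pca(dtc), "degenerate")
  expect_identical(sel, c("a", "b"))

  # nothing passes the eigenvalue criterion -> empty selection -> fallback
  withr::with_seed(12, dtn <- data_table(matrix(rnorm(200, sd = 0.1),
                                                ncol = 2)))
  expect_length(select_relevant_features_pca(dtn), 0)
  expect_warning(res <- dp_downsample(dtn, run_config(size = 10, seed = 0,
                                                      n_trials = 3,
                                                      pca_importance = TRUE)),
                 "falling back")
  expect_identical(res$variables_assessed, dtn$feature_names)
})

test_that("equal-variance variables stay within the feature set", {
  withr::with_seed(14, dt <- data_table(matrix(rnorm(400, sd = 2), ncol = 2)))
  expect_true(all(select_relevant_features_pca(dt) %in% dt$feature_names))
})

test_that("invalid configurations are rejected", {
  dt <- tiny_two_class()
  expect_error(run_config(size = 0), "positive")
  expect_error(run_config(size = 5, n_trials = 0), ">= 1")
  expect_error(run_config(size = 5, metric_id = "nope"), "legal tokens")
  expect_error(dp_downsample(dt, run_config(size = 8)), "smaller than n")
})
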