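cv_config <- function(...) {
  cfg <- train_config(hidden = c(32, 16), max_epochs = 30,
                      batch_size = 16, l1_coef = 0.01, l2_coef = 0.01)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

test_that("stratified folds are balanced and cross-validation is accurate
           on separable data", {
  sim <- simulate_dataset(simulation_config(
    n_samples_per_class = rep(20, 4), n_genes = 400,
    n_specific_per_pair = 15, effect_size = 3, seed = 91))
  cv <- cross_validate(sim$dataset, k = 5, config = cv_config(), seed = 17)
  expect_equal(cv$policy, "per_fold")
  expect_length(cv$folds, 5)
  # per-class stratification: 20 samples over 5 folds -> 4 per fold,
  # so every test fold has 16 samples
  expect_equal(vapply(cv$folds, function(f) f$n_test, numeric(1)),
               rep(16, 5))
  acc <- cv$aggregate$mean[cv$aggregate$metric == "overall_accuracy"]
  expect_gte(acc, 95)
})

test_that("global selection policy runs and reports itself", {
  sim <- simulate_dataset(simulation_config(
    n_samples_per_class = rep(10, 4), n_genes = 200,
    n_specific_per_pair = 10, effect_size = 3, seed = 92))
  cv <- cross_validate(sim$dataset, k = 2, selection_policy = "global",
                       config = cv_config(max_epochs = 15), seed = 5)
  expect_equal(cv$policy, "global")
  # same gene count in every fold under global selection
  expect_length(unique(vapply(cv$folds, function(f) f$n_genes,
                              numeric(1))), 1L)
  expect_error(cross_validate(sim$dataset, k = 11), "k <=")
})

test_that("holdout_split is stratified, disjoint, covering and seeded", {
  set.seed(1)
  n_per <- c(120, 220, 70, 102)            # 512 samples, unbalanced
  labels <- rep(cms_levels(), times = n_per)
  ds <- expression_dataset(matrix(rnorm(5 * 512), 5, 512),
                           sprintf("g%d", 1:5), sprintf("s%d", 1:512),
                           labels = labels)
  sp <- holdout_split(ds, 0.9, seed = 2)
  expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids),
                  ds$sample_ids)
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
  # 9:1 on 512 samples gives a test set of 51-52 by per-class rounding
  expect_true(ncol(sp$test$values) %in% c(51, 52))
  tr_tab <- table(sp$train$labels)
  expect_equal(as.numeric(round(tr_tab /
                                  table(ds$labels)[names(tr_tab)], 1)),
               rep(0.9, 4))
  sp2 <- holdout_split(ds, 0.9, seed = 2)
  expect_identical(sp$train$sample_ids, sp2$train$sample_ids)
  expect_error(holdout_split(ds, 1), "strictly between")
})

test_that("regularizer_scan tabulates one row per grid point and a single
           point reduces to plain CV", {
  sim <- simulate_dataset(simulation_config(
    n_samples_per_class = rep(10, 4), n_genes = 200,
    n_specific_per_pair = 10, effect_size = 3, seed = 93))
  tab <- regularizer_scan(sim$dataset, coef_grid = c(0.05, 0.3), k = 2,
                          config = cv_config(max_epochs = 10), seed = 3)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$coef, c(0.05, 0.3))
  cfg <- cv_config(max_epochs = 10)
  cfg$l1_coef <- 0.05; cfg$l2_coef <- 0.05
  cv <- cross_validate(sim$dataset, k = 2, config = cfg, seed = 3)
  expect_equal(tab$mean_accuracy[1],
               cv$aggregate$mean[cv$aggregate$metric == "overall_accuracy"])
})

test_that("distance correlation matches the double-loop oracle", {
  set.seed(71)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 3), 20, 3)
    Y <- matrix(rnorm(20 * 3), 20, 3)
    expect_equal(as.numeric(distance_correlation(X, Y)), brute_dcor(X, Y),
                 tolerance = 1e-10)
    expect_equal(as.numeric(distance_correlation(X, Y)),
                 as.numeric(distance_correlation(Y, X)), tolerance = 1e-12)
  }
  X <- matrix(rnorm(15), 15, 1)
  expect_equal(as.numeric(distance_correlation(X, X)), 1, tolerance = 1e-12)
  cst <- distance_correlation(matrix(1, 15, 1), X)
  expect_equal(as.numeric(cst), 0)
  expect_true(attr(cst, "degenerate"))
  expect_error(distance_correlation(X, matrix(0, 3, 1)), "same number")
})

test_that("dataset distance correlation works over shared gene profiles", {
  sim1 <- simulate_dataset(simulation_config(
    n_samples_per_class = rep(10, 4), n_genes = 150,
    n_specific_per_pair = 5, seed = 61))
  # a cohort of a different size measuring an overlapping gene panel
  sim2 <- simulate_dataset(simulation_config(
    n_samples_per_class = rep(7, 4), n_genes = 150,
    n_specific_per_pair = 5, seed = 62))
  d <- dataset_distance_correlation(sim1$dataset, sim2$dataset)
  expect_gte(as.numeric(d), 0)
  expect_lte(as.numeric(d), 1)
  # identical dataset: correlation 1
  expect_equal(as.numeric(
    dataset_distance_correlation(sim1$dataset, sim1$dataset)), 1,
    tolerance = 1e-12)
})

test_that("top_weight_genes ranks by absolute weight with stable ties", {
  p <- network_params(5, hidden = c(4, 3), dropout_keep_p = 1)
  genes <- c("g1", "g2", "g3", "g4", "g5")
  p$W1 <- matrix(0, 4, 5)
  p$W1[1, ] <- c(0.1, -5, 0.3, 0.3, 0.2)
  top <- top_weight_genes(p, neuron_indices = 1, k = 5, gene_ids = genes)
  # dominant weight first; tie between g3/g4 broken by gene id
  expect_equal(top$neuron_1, c("g2", "g3", "g4", "g5", "g1"))
  # k = d_in returns a permutation of the genes
  expect_setequal(top$neuron_1, genes)
  # ranking invariant under positive rescaling
  p2 <- p
  p2$W1 <- p$W1 * 7.3
  expect_identical(top_weight_genes(p2, 1, 5, gene_ids = genes), top)
  expect_error(top_weight_genes(p, 9, 2, gene_ids = genes), "out of range")
  expect_error(top_weight_genes(p, 1, 99, gene_ids = genes), "exceeds")
})
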