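test_that("the study-sized cohort splits into balanced stratified partitions", {
  labels <- rep(c("malignant", "benign"), c(51, 62))
  split <- stratified_split(labels, seed = 7)
  sizes <- as.vector(table(split$assignment))
  expect_equal(sort(sizes, decreasing = TRUE), c(23L, 23L, 23L, 22L, 22L))
  # per-partition class counts within one of proportional allocation
  mal <- tapply(labels == "malignant", split$assignment, sum)
  expect_true(all(mal %in% c(10L, 11L)))
  ben <- tapply(labels == "benign", split$assignment, sum)
  expect_true(all(ben %in% c(12L, 13L)))
})

test_that("small balanced cohorts split evenly and seeds reproduce", {
  labels <- rep(c("malignant", "benign"), each = 5)
  s1 <- stratified_split(labels, seed = 3)
  expect_equal(as.vector(table(s1$assignment)), rep(2L, 5))
  mal <- tapply(labels == "malignant", s1$assignment, sum)
  expect_true(all(mal == 1L))
  s2 <- stratified_split(labels, seed = 3)
  expect_identical(s1$assignment, s2$assignment)
  expect_error(stratified_split(rep(c("malignant", "benign"), c(4, 20))),
               "at least")
})

test_that("cross-validation trains four fold models without test leakage", {
  co <- toy_cohort(30, seed = 8)
  split <- stratified_split(co$labels, seed = 2)
  cfg <- train_config(learning_rate = 0.005, batch_size = 4,
                      l2_lambda = 0, max_epochs = 4, patience = 3,
                      seed = 11)
  cv <- cross_validate(tiny_spec(), co$tensors, co$labels, split, cfg)
  expect_length(cv$fold_models, 4L)
  expect_true(all(cv$fold_auc >= 0 & cv$fold_auc <= 1))
  expect_equal(cv$mean_auc, mean(cv$fold_auc))
  expect_equal(cv$sd_auc, sd(cv$fold_auc))
  # the test partition never feeds training, validation or normalisation
  ids <- names(split$assignment)
  test_ids <- ids[split$assignment == split$test_partition]
  cv_ids <- ids[split$assignment %in% split$cv_partitions]
  expect_length(intersect(test_ids, cv_ids), 0L)
  expect_setequal(c(test_ids, cv_ids), ids)
  # fold training sizes cover the three complementary partitions
  part_sizes <- table(split$assignment)[split$cv_partitions]
  expect_equal(cv$train_sizes,
               as.integer(sum(part_sizes) - part_sizes))
})

test_that("scoring validation subjects by true uptake separates folds well", {
  # oracle scorer on high-contrast toys: every fold AUC is high
  co <- toy_cohort(30, noise = 0.05, seed = 12)
  split <- stratified_split(co$labels, seed = 4)
  ids <- names(split$assignment)
  for (k in 1:4) {
    va <- ids[split$assignment == split$cv_partitions[k]]
    score <- vapply(co$tensors[va], max, numeric(1))
    expect_gt(empirical_roc(score, co$labels[va])$auc, 0.9)
  }
})

test_that("augmented training keeps validation on original tensors", {
  co <- toy_cohort(30, side = 6, seed = 9)
  split <- stratified_split(co$labels, seed = 5)
  cfg <- train_config(learning_rate = 0.01, batch_size = 8, l2_lambda = 0,
                      max_epochs = 2, patience = 1, seed = 3)
  plan <- augmentation_plan(
    minority = list(n_translations = 2L, n_rotations_per_axis = 1L,
                    noise_counts = c(1L, 0L, 0L)),
    majority = list(n_translations = 1L, n_rotations_per_axis = 1L,
                    noise_counts = c(1L, 0L, 0L)),
    translation_range_vox = 2L, seed = 6)
  spec6 <- tiny_spec(side = 6L)
  cv <- cross_validate(spec6, co$tensors, co$labels, split, cfg,
                       augment_plan = plan)
  expect_length(cv$fold_models, 4L)
  # original fold training sizes are reported, not augmented counts
  part_sizes <- table(split$assignment)[split$cv_partitions]
  expect_equal(cv$train_sizes, as.integer(sum(part_sizes) - part_sizes))
})

test_that("repeated cross-validation reproduces and aggregates", {
  co <- toy_cohort(30, side = 6, seed = 10)
  split <- stratified_split(co$labels, seed = 6)
  cfg <- train_config(learning_rate = 0.01, batch_size = 8, l2_lambda = 0,
                      max_epochs = 2, patience = 1, seed = 4)
  spec6 <- tiny_spec(side = 6L)
  single <- cross_validate(spec6, co$tensors, co$labels, split, cfg)
  rep1 <- repeat_cv(spec6, co$tensors, co$labels, split, cfg,
                    iterations = 1L)
  expect_equal(rep1$mean_auc, single$mean_auc)
  expect_equal(rep1$runs[[1]]$fold_auc, single$fold_auc)
  rep2 <- repeat_cv(spec6, co$tensors, co$labels, split, cfg,
                    iterations = 2L)
  expect_equal(rep2$mean_auc,
               mean(vapply(rep2$runs, `[[`, numeric(1), "mean_auc")))
})

test_that("the ensemble weights by training-partition size and averages", {
  co <- toy_cohort(30, side = 6, seed = 11)
  split <- stratified_split(co$labels, seed = 7)
  cfg <- train_config(learning_rate = 0.01, batch_size = 8, l2_lambda = 0,
                      max_epochs = 2, patience = 1, seed = 5)
  spec6 <- tiny_spec(side = 6L)
  cv <- cross_validate(spec6, co$tensors, co$labels, split, cfg)
  ens <- build_ensemble(cv)
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  expect_equal(ens$weights, cv$train_sizes / sum(cv$train_sizes))

  # four identical fold models: ensemble equals any single model
  cv_same <- cv
  for (k in 1:4) {
    cv_same$fold_models[[k]] <- cv$fold_models[[1]]
    cv_same$fold_stats[[k]] <- cv$fold_stats[[1]]
  }
  ens_same <- build_ensemble(cv_same)
  x <- co$tensors[1:3]
  single <- forward(cv$fold_models[[1]],
                    lapply(x, apply_minmax, stats = cv$fold_stats[[1]]))
  expect_equal(predict(ens_same, x), single, tolerance = 1e-12)

  # the documented 113-subject arithmetic: sizes {23,23,22,22} on the CV
  # partitions give training sizes {67,67,68,68} and weights /270
  fake <- cv
  fake$train_sizes <- c(67L, 67L, 68L, 68L)
  w <- build_ensemble(fake)$weights
  expect_equal(w, c(67, 67, 68, 68) / 270)
})
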