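feature_table <- function(n_per_class = 40, seed = 0) {
  dataset_features(generate_labeled_dataset(
    population_model(seed = seed), n_per_class = n_per_class))
}

test_that("stratified splitting is exact, reproducible and tooth-disjoint", {
  feats <- feature_table(20)  # 40 teeth
  sp <- split_dataset(feats, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 28)
  expect_equal(nrow(sp$test), 12)
  expect_length(intersect(sp$train$tooth_id, sp$test$tooth_id), 0)
  # per-class counts preserved within one sample of the global ratio
  expect_equal(as.vector(table(sp$train$label)), c(14, 14))
  sp2 <- split_dataset(feats, 0.7, seed = 1)
  expect_identical(sp$train$tooth_id, sp2$train$tooth_id)
  expect_error(split_dataset(feats[feats$label == "ND", ], 0.7), "both")
})

test_that("min-max normalization maps training extremes to [0,1] without leakage", {
  x <- matrix(c(3.9e3, 7.5e4, 1e4), ncol = 1, dimnames = list(NULL, "r1"))
  nrm <- fit_normalizer(x[1:2, , drop = FALSE])
  expect_equal(as.vector(apply_normalizer(x, nrm)),
               c(0, 1, (1e4 - 3.9e3) / (7.5e4 - 3.9e3)))
  mid <- (3.9e3 + 7.5e4) / 2
  expect_equal(as.vector(apply_normalizer(matrix(mid), nrm)), 0.5)
  # values beyond the training range are not clipped
  expect_lt(apply_normalizer(matrix(1e3), nrm)[1], 0)
  # the transform depends only on the data it was fitted on
  nrm2 <- fit_normalizer(x[1:2, , drop = FALSE])
  expect_identical(nrm, nrm2)
  expect_error(fit_normalizer(matrix(c(1, 1), ncol = 1)), "constant")
})

test_that("the MLP separates well-separated classes and is seed-deterministic", {
  # nearly noiseless class centres: linearly separable in feature space
  tight <- dataset_features(generate_labeled_dataset(
    population_model(log_sd = 1.05, n_sd = 0.005), n_per_class = 10))
  model <- train_mlp_classifier(tight, mlp_config())
  pr <- predict(model, tight)
  expect_equal(mean(pr$label == tight$label), 1)
  # determinism under a fixed seed
  feats <- feature_table(20)
  m1 <- train_mlp_classifier(feats, mlp_config(seed = 5))
  m2 <- train_mlp_classifier(feats, mlp_config(seed = 5))
  expect_identical(predict(m1, feats)$prob, predict(m2, feats)$prob)
  # probability output in [0,1]; boundary tie goes to DM
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_equal(ifelse(0.5 >= 0.5, "DM", "ND"), "DM")
  expect_error(predict(m1, feats[, c("r1", "r2")]), "features")
})

test_that("a 70/30 train/test run reaches realistic held-out accuracy", {
  feats <- feature_table(40)  # 80 teeth -> 24 test samples
  sp <- split_dataset(feats, 0.7, seed = 0)
  expect_equal(nrow(sp$test), 24)
  model <- train_mlp_classifier(sp$train, mlp_config())
  pr <- predict(model, sp$test)
  acc <- mean(pr$label == sp$test$label)
  expect_gte(acc, 0.75)
  expect_lte(acc, 1.0)
  # class-centre inputs classify correctly after training
  ctr <- data.frame(r1 = c(3.9e3, 7.5e4), r2 = c(2.6e7, 3.4e7),
                    q = c(3.3e-7, 2.1e-7))
  expect_equal(predict(model, ctr)$label, c("ND", "DM"))
})

test_that("cross-validation is stratified, consistent and stable", {
  feats <- feature_table(40)
  cv <- cross_validate(feats, mlp_config(), k = 5, seed = 3)
  expect_equal(nrow(cv$per_split), 5)
  expect_equal(cv$summary$mean[1], mean(cv$per_split$accuracy), tolerance = 1e-12)
  expect_equal(cv$summary$sd[1], sd(cv$per_split$accuracy), tolerance = 1e-12)
  expect_lte(cv$summary$sd[1], 0.15)
  expect_gte(cv$summary$mean[1], 0.75)
  expect_error(cross_validate(feats[c(1:4, 41:44), ], k = 5), "fewer")
  expect_error(cross_validate(feats[1:10, ], k = 5), "both")
})

test_that("adding the CPE exponent as a feature does not improve CV accuracy", {
  feats <- feature_table(40)
  base <- cross_validate(feats, mlp_config(), seed = 11)
  with_n <- cross_validate(feats, mlp_config(features = c("r1", "r2", "q", "n")),
                           seed = 11)
  expect_lte(with_n$summary$mean[1], base$summary$mean[1] + 0.02)
})
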