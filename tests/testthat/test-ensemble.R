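separable_data <- function(n_per_class = 100, shift = 5, seed = 1) {
  dplyr::bind_rows(
    feature_records(n_per_class, shift = 0, plate = "train-ns",
                    condition = "non-salt", seed = seed),
    feature_records(n_per_class, shift = shift, plate = "train-s",
                    condition = "salt", seed = seed + 1)
  )
}

test_that("well-separated classes are learned by nearly every member", {
  train <- separable_data(100, shift = 5, seed = 1)
  held <- separable_data(100, shift = 5, seed = 50)
  model <- train_ensemble(train, subset = "all", seed = 7)
  labels <- predict_seeds(model, held)
  acc <- rowMeans(labels == matrix(held$condition, nrow(labels),
                                   nrow(held), byrow = TRUE))
  expect_gte(sum(acc >= 0.95), 11)
  # training accuracy at least matches held-out accuracy overall
  train_labels <- predict_seeds(model, train)
  train_acc <- mean(train_labels == matrix(train$condition,
                                           nrow(train_labels),
                                           nrow(train), byrow = TRUE))
  expect_gte(train_acc + 1e-8, mean(labels == matrix(held$condition,
                                                     nrow(labels),
                                                     nrow(held),
                                                     byrow = TRUE)) - 0.02)
})

test_that("identical class distributions give chance-level accuracy", {
  train <- separable_data(100, shift = 0, seed = 2)
  held <- separable_data(100, shift = 0, seed = 60)
  model <- train_ensemble(train, subset = "all", seed = 3)
  labels <- predict_seeds(model, held)
  consensus_acc <- mean(
    ifelse(colMeans(labels == "salt") > 0.5, "salt", "non-salt") ==
      held$condition
  )
  # 95% binomial interval around 0.5 for n = 200 seeds
  ci <- qbinom(c(0.025, 0.975), 200, 0.5) / 200
  expect_gte(consensus_acc, ci[1])
  expect_lte(consensus_acc, ci[2])
})

test_that("training and prediction are deterministic given the seed", {
  train <- separable_data(40, shift = 1, seed = 4)
  test <- separable_data(30, shift = 1, seed = 5)
  m1 <- train_ensemble(train, subset = "all", seed = 11)
  m2 <- train_ensemble(train, subset = "all", seed = 11)
  expect_identical(predict_seeds(m1, test), predict_seeds(m2, test))
})

test_that("attribute subsets restrict the model to the documented columns", {
  train <- separable_data(40, shift = 2, seed = 6)
  for (subset in c("all", "morpho", "color")) {
    m <- train_ensemble(train, subset = subset, seed = 1)
    expect_true(all(m$columns %in% feature_columns(subset)))
  }
  # a color-only model works without morphological columns present
  m <- train_ensemble(train, subset = "color", seed = 1)
  test <- separable_data(10, shift = 2, seed = 8)
  test_color <- test[, c("plate", feature_columns("color"))]
  expect_silent(predict_seeds(m, test_color))
})

test_that("degenerate training inputs raise typed errors", {
  one_class <- feature_records(30, condition = "salt", seed = 9)
  expect_error(train_ensemble(one_class, "all", seed = 1),
               class = "seedsalt_training_error")
  train <- separable_data(20, shift = 1, seed = 10)
  train$q2r[3] <- NA
  expect_error(train_ensemble(train, "all", seed = 1),
               class = "seedsalt_input_error")
  m <- train_ensemble(separable_data(20, shift = 1, seed = 12), "all",
                      seed = 1)
  expect_error(predict_seeds(m, separable_data(5)[, 1:4]),
               class = "seedsalt_input_error")
})

test_that("prediction is a pure per-seed function", {
  train <- separable_data(40, shift = 2, seed = 13)
  m <- train_ensemble(train, "all", seed = 5)
  test <- separable_data(10, shift = 2, seed = 14)
  dup <- dplyr::bind_rows(test, test[1, ])
  labels <- predict_seeds(m, dup)
  expect_identical(labels[, ncol(labels)], labels[, 1])

  empty <- predict_seeds(m, test[0, ])
  expect_equal(dim(empty), c(13L, 0L))
  expect_identical(rownames(empty), ensemble_algorithms())
})

test_that("plate consensus follows the strict greater-than-50 rule", {
  algs <- ensemble_algorithms()
  all_salt <- matrix("salt", 13, 6, dimnames = list(algs, NULL))
  p <- classify_plate(all_salt, plate = "a")
  expect_equal(p$consensus, 100)
  expect_identical(p$status, "salt")

  none <- matrix("non-salt", 13, 6, dimnames = list(algs, NULL))
  p0 <- classify_plate(none, plate = "b")
  expect_equal(p0$consensus, 0)
  expect_identical(p0$status, "non-salt")

  # per-algorithm percentages (60,40,50,70,30,55,45,65,35,50,60,40,50)
  # average exactly 50 -> non-salt
  pct <- c(60, 40, 50, 70, 30, 55, 45, 65, 35, 50, 60, 40, 50)
  labels <- do.call(rbind, lapply(pct, function(p) {
    rep(c("salt", "non-salt"), c(p / 5, 20 - p / 5))
  }))
  rownames(labels) <- algs
  res <- classify_plate(labels, plate = "c")
  expect_equal(res$consensus, 50)
  expect_identical(res$status, "non-salt")

  expect_error(classify_plate(all_salt[, 0]),
               class = "seedsalt_classification_error")
})

test_that("consensus is permutation invariant and complements correctly", {
  withr::with_seed(15, {
    algs <- ensemble_algorithms()
    labels <- matrix(sample(c("salt", "non-salt"), 13 * 40, replace = TRUE),
                     13, 40, dimnames = list(algs, NULL))
    base <- classify_plate(labels)
    # permute algorithms and seeds
    perm <- classify_plate(labels[sample(13), sample(40)])
    expect_equal(perm$consensus, base$consensus)
    # relabeling salt <-> non-salt maps consensus c to 100 - c
    flipped <- ifelse(labels == "salt", "non-salt", "salt")
    dimnames(flipped) <- dimnames(labels)
    expect_equal(classify_plate(flipped)$consensus, 100 - base$consensus)
  })
})

test_that("zero_rule predicts the majority class and stays out of the consensus", {
  train <- dplyr::bind_rows(
    feature_records(30, condition = "salt", seed = 16),
    feature_records(10, condition = "non-salt", seed = 17)
  )
  zr <- zero_rule(train)
  expect_identical(zr(train[1:5, ]), rep("salt", 5))
  expect_false("ZeroR" %in% ensemble_algorithms())
  expect_length(ensemble_algorithms(), 13L)
})
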