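test_that("feature matrix has the 18-column contract and lag alignment", {
  s <- generate_outdoor_series(outdoor_climate_config(seed = 1))
  fm <- build_feature_matrix(s)
  expect_identical(ncol(fm$X), 18L)
  expect_identical(colnames(fm$X)[1:6], c("T_a", "T_d", "v", "p", "G", "A_G"))
  expect_identical(colnames(fm$X)[7:9],
                   c("T_a_lag3", "G_lag3", "A_G_lag3"))
  # first usable row is 24 h after series start
  expect_identical(fm$timestamps[1], s$timestamp[9])
  expect_identical(nrow(fm$X), nrow(s) - 8L)
  # lag columns really are lagged copies
  expect_identical(fm$X[, "T_a_lag24"], s$T_a[1:(nrow(s) - 8)])
  expect_identical(fm$X[, "G_lag3"], s$G[8:(nrow(s) - 1)])
})

test_that("feature matrix boundary and degenerate cases", {
  expect_identical(nrow(build_feature_matrix(constant_series(8))$X), 0L)
  expect_error(build_feature_matrix(constant_series(7)), "shorter")
  fm <- build_feature_matrix(constant_series(16, T_a = 10))
  lag_cols <- grep("T_a_lag", colnames(fm$X))
  expect_true(all(fm$X[, lag_cols] == 10))
})

test_that("splits are disjoint 80/10/10 covers, reproducible by seed", {
  sp <- split_dataset(1000, 42)
  expect_identical(lengths(sp[c("train", "validation", "test")]),
                   c(train = 800L, validation = 100L, test = 100L))
  expect_identical(split_dataset(1000, 42), sp)
  expect_false(identical(split_dataset(1000, 43)$train, sp$train))
  sp10 <- split_dataset(10, 1)
  expect_identical(lengths(sp10[c("train", "validation", "test")]),
                   c(train = 8L, validation = 1L, test = 1L))
  for (n in c(10, 37, 101, 1000)) {
    for (seed in 1:3) {
      s <- split_dataset(n, seed)
      all_idx <- c(s$train, s$validation, s$test)
      expect_identical(sort(all_idx), seq_len(n))
      expect_identical(anyDuplicated(all_idx), 0L)
    }
  }
  expect_error(split_dataset(9, 1), "n_rows")
})

test_that("a constant target is learned to near-zero error", {
  s <- generate_outdoor_series(outdoor_climate_config(seed = 2))
  fm <- build_feature_matrix(s)
  m <- train_surrogate(fm, rep(21, nrow(fm$X)), seed = 3,
                       hyper = list(max_epochs = 150))
  expect_lte(m$test_mae, 0.05)
})

test_that("training is deterministic and records metadata", {
  s <- generate_outdoor_series(outdoor_climate_config(seed = 6))
  fm <- build_feature_matrix(s)
  set.seed(8)
  y <- 0.4 * fm$X[, "T_a"] + 12 + rnorm(nrow(fm$X), 0.2)
  h <- list(max_epochs = 30)
  m1 <- train_surrogate(fm, y, hyper = h, seed = 5, target = "T_i")
  m2 <- train_surrogate(fm, y, hyper = h, seed = 5, target = "T_i")
  expect_identical(m1$test_mae, m2$test_mae)
  expect_identical(m1$weights, m2$weights)
  expect_identical(dim(m1$weights$W1), c(18L, 16L))
  expect_identical(dim(m1$weights$W2), c(16L, 1L))
  expect_identical(m1$meta$target, "T_i")
  expect_gte(m1$meta$best_epoch, 1L)
  expect_error(train_surrogate(fm, c(y[-1], NA), hyper = h), "non-finite")
})

test_that("prediction matches a hand-computed forward pass", {
  m <- structure(list(
    weights = list(W1 = matrix(0.1, 18, 16), b1 = rep(0.2, 16),
                   W2 = matrix(0.05, 16, 1), b2 = 0.3),
    x_center = rep(1, 18), x_scale = rep(2, 18),
    y_center = 10, y_scale = 4,
    feature_names = paste0("f", 1:18),
    meta = list(target = "T_i")
  ), class = "surrogate_model")
  x <- matrix(seq(0.5, 9, by = 0.5), 1, 18)
  xs <- (x - 1) / 2
  hidden <- 1 / (1 + exp(-(sum(xs * 0.1) + 0.2)))
  manual <- (16 * hidden * 0.05 + 0.3) * 4 + 10
  expect_equal(indoorheat:::predict_scaled(m, x), manual, tolerance = 1e-12)
  # all-zero weights with output bias b predict the unscaled constant
  m$weights$W1[] <- 0; m$weights$b1[] <- 0; m$weights$W2[] <- 0
  m$weights$b2 <- 0.5
  expect_equal(indoorheat:::predict_scaled(m, x), 0.5 * 4 + 10)
})

test_that("shifting the target shifts predictions by the same constant", {
  s <- generate_outdoor_series(outdoor_climate_config(seed = 9))
  fm <- build_feature_matrix(s)
  set.seed(10)
  y <- 0.5 * fm$X[, "T_a"] + rnorm(nrow(fm$X), sd = 0.3)
  sp <- split_dataset(nrow(fm$X), 2)
  h <- list(max_epochs = 15)
  ma <- train_surrogate(fm, y, sp, hyper = h, seed = 5)
  mb <- train_surrogate(fm, y + 7, sp, hyper = h, seed = 5)
  shift <- indoorheat:::predict_scaled(mb, fm$X) -
    indoorheat:::predict_scaled(ma, fm$X)
  expect_equal(shift, rep(7, nrow(fm$X)), tolerance = 1e-8)
})

test_that("evaluate_mae is the plain mean absolute error", {
  m <- structure(list(
    weights = list(W1 = matrix(0, 3, 16), b1 = rep(0, 16),
                   W2 = matrix(0, 16, 1), b2 = 0),
    x_center = rep(0, 3), x_scale = rep(1, 3), y_center = 0, y_scale = 1,
    feature_names = paste0("f", 1:3), meta = list(target = "T_i")
  ), class = "surrogate_model")
  X <- matrix(0, 3, 3)
  # zero network predicts 0: MAE of (1,1,5) vs 0 is 7/3
  expect_equal(evaluate_mae(m, X, c(1, 1, 5)), 7 / 3)
  expect_equal(evaluate_mae(m, X, c(0, 0, 0)), 0)
  expect_error(evaluate_mae(m, X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("models serialize to JSON and restore exactly", {
  s <- generate_outdoor_series(outdoor_climate_config(seed = 12))
  fm <- build_feature_matrix(s)
  m <- train_surrogate(fm, fm$X[, "T_a"], hyper = list(max_epochs = 5),
                       seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_surrogate(m, f)
  r <- read_surrogate(f)
  expect_equal(r$weights, m$weights, tolerance = 1e-12)
  expect_equal(indoorheat:::predict_scaled(r, fm$X[1:5, ]),
               indoorheat:::predict_scaled(m, fm$X[1:5, ]), tolerance = 1e-12)
})

test_that("predict_series carries timestamps and checks the contract", {
  s <- generate_outdoor_series(outdoor_climate_config(seed = 13))
  fm <- build_feature_matrix(s)
  m <- train_surrogate(fm, fm$X[, "T_a"], hyper = list(max_epochs = 5),
                       seed = 1)
  pr <- predict_series(m, s)
  expect_identical(nrow(pr), nrow(s) - 8L)
  expect_identical(pr$timestamp, fm$timestamps)
  m$feature_names[1] <- "bogus"
  expect_error(predict_series(m, s), "mismatch")
})
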