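# Normalization, splitting, training contracts and the learnable-identity
# sanity oracle for the LSTM regressor.

test_that("max-abs normalization and its constants behave as specified", {
  v <- seq(0.1, 4, length.out = 101)
  f <- seq(20, 2000, length.out = 101)
  p <- vf_pair(v, f, source = "synthetic")
  nm <- normalize_pairs(list(p))
  expect_equal(nm$norms$v_maxabs, 4)
  expect_equal(nm$norms$f_maxabs, 2000)
  expect_equal(max(nm$velocity), 1)
  expect_equal(max(nm$force), 1)
  expect_true(all(abs(nm$velocity) <= 1) && all(abs(nm$force) <= 1))

  # reusing constants on a half-scale curve
  expect_equal(max(v / 2 / nm$norms$v_maxabs), 0.5)

  # round trip
  pairs <- make_pairs(8, seed = 1)
  nm2 <- normalize_pairs(pairs)
  m <- scrumforce:::pairs_to_matrices(pairs)
  expect_lt(max(abs(nm2$force * nm2$norms$f_maxabs - m$force)), 1e-12 * 4000)

  zero <- vf_pair(rep(0, 101), f, source = "gan")
  expect_error(normalize_pairs(list(zero)), class = "scrumforce_data_error")
})

test_that("the 80/20 split is exhaustive, disjoint and seeded", {
  pairs <- make_pairs(10, seed = 2)
  big <- rep(pairs, 100)  # 1000 pairs
  sp <- split_dataset(big, 0.8, seed = 3)
  expect_length(sp$train, 800)
  expect_length(sp$validation, 200)

  small <- split_dataset(pairs[1:5], 0.8, seed = 3)
  expect_length(small$train, 4)
  expect_length(small$validation, 1)

  sp2 <- split_dataset(big, 0.8, seed = 3)
  expect_identical(vapply(sp$train, function(p) p$meta$trial_id, character(1)),
                   vapply(sp2$train, function(p) p$meta$trial_id, character(1)))

  ids <- function(x) vapply(x, function(p) p$meta$trial_id, character(1))
  sp3 <- split_dataset(pairs, 0.8, seed = 4)
  expect_setequal(c(ids(sp3$train), ids(sp3$validation)), ids(pairs))
  expect_length(intersect(ids(sp3$train), ids(sp3$validation)), 0)

  expect_error(split_dataset(pairs[1:4]), class = "scrumforce_data_error")
})

test_that("the regressor learns the identity task to excellent correlation", {
  pairs <- make_ramp_pairs(80, seed = 3)
  m <- train_predictor(pairs[1:60], pairs[61:70],
                       rnn_config(layer_cells = 16, learning_rate = 0.01,
                                  epochs = 120, patience = 30, seed = 1))
  pred <- predict(m, pairs[71:80])
  for (i in 1:10)
    expect_gt(cor(pred[i, ], pairs[[70 + i]]$force), 0.99)
})

test_that("training contracts: early stopping, determinism, prediction shape", {
  pairs <- make_ramp_pairs(30, seed = 4)
  cfg0 <- rnn_config(layer_cells = 8, epochs = 15, patience = 0, seed = 2)
  m0 <- train_predictor(pairs[1:24], pairs[25:30], cfg0)
  # patience 0: stops at the first epoch that fails to improve
  expect_lte(m0$stopped_epoch, 15)
  expect_equal(nrow(m0$history), m0$stopped_epoch)
  # restored weights are never worse than the best epoch seen
  expect_equal(m0$best_val_loss, min(m0$history$val_loss))

  cfg1 <- rnn_config(layer_cells = 8, epochs = 5, patience = 5, seed = 2)
  m1 <- train_predictor(pairs[1:24], pairs[25:30], cfg1)
  m2 <- train_predictor(pairs[1:24], pairs[25:30], cfg1)
  expect_identical(m1$history, m2$history)

  out <- predict_force(m1, pairs[[1]]$velocity)
  expect_length(out, 101)
  expect_true(all(out >= 0))          # ReLU head
  expect_identical(out, predict_force(m1, pairs[[1]]$velocity))

  mat <- predict(m1, pairs[1:3])
  expect_equal(dim(mat), c(3, 101))
  expect_error(predict_force(m1, rnorm(50)), class = "scrumforce_shape_error")
  expect_error(predict_force(m1, c(rnorm(100), NA)),
               class = "scrumforce_data_error")
})

test_that("grid search enumerates the full space and returns the argmin", {
  pairs <- make_ramp_pairs(20, seed = 5)
  # full space cardinality: 3 layer counts x 3 widths x 3 rates = 27 rows
  gs_card <- expand.grid(layers = 1:3, cells = c(32, 64, 128),
                         lr = c(0.001, 0.002, 0.01))
  expect_equal(nrow(gs_card), 27)

  # tiny space actually trained: single combination returns itself
  gs1 <- grid_search(pairs, layers_options = 1, cells_options = 8,
                     lr_options = 0.01, cv_folds = 2, epochs = 3, patience = 1,
                     seed = 1)
  expect_equal(nrow(gs1$table), 1)
  expect_equal(gs1$best$layer_cells, 8L)
  expect_equal(gs1$best$learning_rate, 0.01)

  # two learning rates: table covers both; scores deterministic under seed
  gs2 <- grid_search(pairs, layers_options = 1, cells_options = 8,
                     lr_options = c(0.005, 0.01), cv_folds = 2, epochs = 3,
                     patience = 1, seed = 1)
  gs2b <- grid_search(pairs, layers_options = 1, cells_options = 8,
                      lr_options = c(0.005, 0.01), cv_folds = 2, epochs = 3,
                      patience = 1, seed = 1)
  expect_equal(nrow(gs2$table), 2)
  expect_identical(gs2$table, gs2b$table)
  expect_true(gs2$table$mean_val_loss[match(gs2$best$learning_rate,
                                            gs2$table$lr)] ==
                min(gs2$table$mean_val_loss))

  expect_error(grid_search(pairs, cv_folds = 50),
               class = "scrumforce_config_error")
})

test_that("held-out error shrinks toward the noise floor as data grow", {
  # deterministic mapping + small amplitude noise, single technique so the
  # ground truth is a pure function of the velocity curve
  cfg <- sim_config(technique_mix = c(CTS = 1), noise_sd = 0.02)
  gen <- function(n, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) simulate_pair(cfg, paste0("p", i)))
  }
  test_set <- gen(60, 99)
  Vt <- t(vapply(test_set, function(x) x$pair$velocity, numeric(101)))
  Gt <- t(vapply(test_set, function(x) x$ground_truth$force, numeric(101)))
  rmse_at <- function(n, epochs) {
    d <- lapply(gen(n, 10), `[[`, "pair")
    sp <- split_dataset(d, 0.8, seed = 1)
    m <- train_predictor(sp$train, sp$validation,
                         rnn_config(layer_cells = c(64, 32),
                                    learning_rate = 0.002, epochs = epochs,
                                    batch_size = 64, patience = 40, seed = 1))
    sqrt(mean((predict_force(m, Vt) - Gt)^2)) / m$norms$f_maxabs
  }
  r_small <- rmse_at(120, 30)
  r_large <- rmse_at(420, 80)
  floor_ <- 0.02 * 0.45  # amplitude noise x mean relative rise of the curves
  expect_lt(r_large, r_small)          # more data, smaller held-out error
  expect_lt(r_large, 3 * floor_)       # approaches the irreducible floor
})
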