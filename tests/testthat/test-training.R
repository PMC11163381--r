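test_that("an oracle predictor achieves exactly zero loss on any batch", {
  set.seed(6)
  for (kind in c("linear", "sigmoid")) {
    sched <- make_schedule(kind, T = 40)
    for (rep in 1:3) {
      y0 <- matrix(runif(16 * 16, -1, 1), 16)
      oracle <- make_oracle_predictor(y0, sched)
      # zero up to float rounding of the forward/inverse scaling
      expect_lt(loss_unsupervised(oracle, list(y0), sched, seed = rep), 1e-20)
      expect_lt(
        loss_supervised(oracle, list(clean = list(y0), noisy = list(y0 + 1)),
          sched, seed = rep), 1e-20)
    }
  }
})

test_that("the zero predictor has unit loss per entry", {
  sched <- make_schedule("linear", T = 50)
  tiles <- replicate(10, matrix(runif(32 * 32, -1, 1), 32), simplify = FALSE)
  n_entries <- 10 * 32 * 32
  loss <- loss_unsupervised(zero_predictor, tiles, sched, seed = 123)
  # E ||eps||^2 / N = 1 for standard normal entries; Var(eps^2) = 2
  expect_lt(abs(loss - 1), 3 * sqrt(2 / n_entries))
})

test_that("losses are bit-identical under a fixed seed", {
  sched <- make_schedule("linear", T = 30)
  p <- tiny_residual(seed = 2)
  tiles <- replicate(4, matrix(runif(64 * 64, -1, 1), 64), simplify = FALSE)
  expect_identical(loss_unsupervised(p, tiles, sched, seed = 5),
    loss_unsupervised(p, tiles, sched, seed = 5))
  pc <- tiny_residual("conditional", seed = 2)
  pairs <- list(clean = tiles, noisy = lapply(tiles, function(m) m + 0.1))
  expect_identical(loss_supervised(pc, pairs, sched, seed = 5),
    loss_supervised(pc, pairs, sched, seed = 5))
  # condition replaced by zeros stays well-defined
  zero_pairs <- list(clean = tiles,
    noisy = lapply(tiles, function(m) m * 0))
  expect_true(is.finite(loss_supervised(pc, zero_pairs, sched, seed = 5)))
})

test_that("supervised losses demand paired tiles and matching modes", {
  sched <- make_schedule("linear", T = 10)
  tiles <- list(matrix(0, 8, 8))
  expect_error(loss_supervised(tiny_residual("conditional"),
    list(clean = tiles), sched), class = "hicdiffuse_config_error")
  expect_error(
    fit_predictor(tiny_residual("conditional"), tibble::tibble(clean = tiles),
      make_schedule("linear", T = 5),
      train_config("supervised", epochs = 1)),
    class = "hicdiffuse_config_error")
  expect_error(
    fit_predictor(tiny_residual("conditional"),
      tibble::tibble(clean = tiles, noisy = tiles),
      make_schedule("linear", T = 5),
      train_config("unsupervised", epochs = 1)),
    class = "hicdiffuse_config_error")
})

make_training_tiles <- function(n_tiles = 24, n = 16, seed = 8) {
  params <- synthetic_params(n_bins = n, tad_boundaries = n %/% 2L,
    read_depth = 500, mode = "single_cell", keep_fraction = 0.2)
  bench <- make_benchmark_set(n_tiles, params, sigma_levels = 0.1, seed = seed)
  tibble::tibble(clean = bench$clean_model, noisy = bench$noisy)
}

test_that("a tiny fit reduces the training loss and selects the best epoch", {
  data <- make_training_tiles()
  sched <- make_schedule("linear", T = 20)
  p <- build_residual_predictor(8, 2, time_dim = 16, seed = 1)
  fit <- fit_predictor(p, data, sched,
    train_config("unsupervised", epochs = 8, batch_size = 4,
      learning_rate = 1e-3, seed = 3))
  h <- fit$history
  expect_equal(nrow(h), 8L)
  expect_lt(h$train_loss[8], h$train_loss[1])
  expect_equal(fit$best_criterion, min(h$val_criterion))
  expect_equal(fit$best_epoch, h$epoch[which.min(h$val_criterion)])
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$parameters, count_parameters(fit$predictor))
})

test_that("training histories are bit-identical under one seed", {
  data <- make_training_tiles(n_tiles = 12)
  sched <- make_schedule("linear", T = 15)
  run <- function() {
    fit_predictor(build_residual_predictor(8, 1, time_dim = 16, seed = 2),
      data, sched,
      train_config("unsupervised", epochs = 3, batch_size = 4, seed = 7))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$history$val_criterion, f2$history$val_criterion)
  expect_identical(f1$predictor$params, f2$predictor$params)
})

test_that("supervised fitting conditions on the noisy tiles", {
  data <- make_training_tiles(n_tiles = 12)
  sched <- make_schedule("linear", T = 15)
  fit <- fit_predictor(
    build_residual_predictor(8, 1, mode = "conditional", time_dim = 16,
      seed = 2),
    data, sched,
    train_config("supervised", epochs = 3, batch_size = 4, seed = 7))
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("divergent training aborts with a diagnostic", {
  data <- make_training_tiles(n_tiles = 8)
  sched <- make_schedule("linear", T = 10)
  expect_error(
    fit_predictor(build_residual_predictor(8, 1, time_dim = 16, seed = 1),
      data, sched,
      train_config("unsupervised", epochs = 6, batch_size = 4,
        learning_rate = 1e8, seed = 1)),
    class = "hicdiffuse_divergence_error")
})

test_that("checkpoints round-trip the fitted model", {
  data <- make_training_tiles(n_tiles = 8)
  sched <- make_schedule("linear", T = 10)
  fit <- fit_predictor(build_residual_predictor(8, 1, time_dim = 16, seed = 2),
    data, sched, train_config("unsupervised", epochs = 2, batch_size = 4,
      seed = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(back$predictor$params, fit$predictor$params)
  expect_identical(back$history, fit$history)
  y <- matrix(rnorm(64), 8)
  expect_identical(predict_noise(back$predictor, y, 3),
    predict_noise(fit$predictor, y, 3))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), class = "hicdiffuse_io_error")
})
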