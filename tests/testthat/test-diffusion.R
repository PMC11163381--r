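test_that("schedules reproduce the closed-form toy cases", {
  s <- make_schedule("linear", T = 2, beta_start = 0.1, beta_end = 0.2)
  expect_equal(s$alpha, c(0.9, 0.8))
  expect_equal(s$alpha_bar, c(0.9, 0.72))
  expect_equal(s$sigma_tilde, c(sqrt(0.1), sqrt(0.28)))

  s1 <- make_schedule("linear", T = 1, beta_start = 0.05, beta_end = 0.05)
  expect_equal(s1$alpha_bar, 1 - 0.05)
})

test_that("alpha_bar matches a sequential-product oracle and decreases strictly", {
  for (kind in c("linear", "sigmoid")) {
    s <- make_schedule(kind, T = 1000)
    prod_oracle <- numeric(1000)
    acc <- 1
    for (t in 1:1000) {
      acc <- acc * (1 - s$beta[t])
      prod_oracle[t] <- acc
    }
    expect_equal(s$alpha_bar, prod_oracle, tolerance = 1e-12)
    expect_true(all(diff(s$alpha_bar) < 0))
    expect_true(all(s$beta > 0 & s$beta < 1))
    expect_equal(s$alpha, 1 - s$beta)
    expect_equal(s$sigma_tilde^2, 1 - s$alpha_bar)
    expect_true(s$alpha_bar[1000] > 0 && s$alpha_bar[1] < 1)
  }
  expect_error(make_schedule("linear", T = 0), class = "hicdiffuse_range_error")
  expect_error(make_schedule("linear", beta_start = 0.5, beta_end = 0.1),
    class = "hicdiffuse_range_error")
})

test_that("the sigmoid schedule ramps slowly at both ends", {
  s <- make_schedule("sigmoid", T = 100, beta_start = 1e-4, beta_end = 0.02)
  d <- diff(s$beta)
  expect_lt(d[1], d[50])          # flat start, steep middle
  expect_lt(d[98], d[50])         # flat end
  expect_equal(min(s$beta), 1e-4 + (0.02 - 1e-4) * plogis(-6))
})

test_that("forward_sample evaluates the printed linear combination", {
  s <- make_schedule("linear", T = 2, beta_start = 0.1, beta_end = 0.2)
  y0 <- matrix(0.6, 1, 1)
  # abar_2 = 0.72, eps = 1
  yt <- forward_sample(y0, 2, s, eps = matrix(1, 1, 1))
  expect_equal(yt[1, 1], 1.0382671446672323, tolerance = 1e-9)
  # eps = 0 leaves pure shrinkage
  expect_equal(forward_sample(y0, 2, s, eps = matrix(0, 1, 1))[1, 1],
    sqrt(0.72) * 0.6)
  expect_error(forward_sample(y0, 3, s), class = "hicdiffuse_range_error")
  expect_error(forward_sample(y0, 1, s, eps = matrix(0, 2, 2)),
    class = "hicdiffuse_shape_error")
})

test_that("forward marginals match the closed form within Monte-Carlo error", {
  s <- make_schedule("linear", T = 1000)
  t_mid <- 500L
  set.seed(10)
  y0 <- matrix(runif(64, -1, 1), 8)
  n_draw <- 10000L
  draws <- vapply(seq_len(n_draw), function(i) forward_sample(y0, t_mid, s),
    matrix(0, 8, 8))
  ab <- s$alpha_bar[t_mid]
  centred <- sweep(matrix(draws, 64, n_draw), 1, sqrt(ab) * as.vector(y0))
  z <- as.vector(centred)
  sd_true <- sqrt(1 - ab)
  expect_lt(abs(mean(z)), 3 * sd_true / sqrt(length(z)))
  expect_lt(abs(sd(z) - sd_true), 3 * sd_true / sqrt(2 * length(z)))
})

test_that("posterior mean matches the algebraic oracle", {
  s <- make_schedule("linear", T = 50)
  expect_equal(posterior_mean(matrix(0, 3, 3), matrix(0, 3, 3), 10, s)$mu,
    matrix(0, 3, 3))
  # final reverse step is noiseless in both variance variants
  expect_equal(posterior_mean(matrix(1, 2, 2), matrix(0, 2, 2), 1, s)$sigma, 0)
  expect_equal(posterior_mean(matrix(1, 2, 2), matrix(0, 2, 2), 1, s,
    variance = "beta_tilde")$sigma, 0)

  set.seed(2)
  y0 <- matrix(runif(25, -1, 1), 5)
  eps <- matrix(rnorm(25), 5)
  for (t in c(2L, 17L, 50L)) {
    yt <- forward_sample(y0, t, s, eps = eps)
    mu <- posterior_mean(yt, eps, t, s)$mu
    ab_prev <- s$alpha_bar[t - 1L]
    expected <- sqrt(ab_prev) * y0 +
      sqrt(s$alpha[t]) * (1 - ab_prev) / sqrt(1 - s$alpha_bar[t]) * eps
    expect_equal(mu, expected, tolerance = 1e-10)
  }
  expect_error(posterior_mean(matrix(0, 2, 2), matrix(0, 3, 3), 1, s),
    class = "hicdiffuse_shape_error")
})

test_that("a perfect noise predictor inverts the forward process", {
  set.seed(5)
  y0 <- matrix(runif(64, -1, 1), 8)
  for (kind in c("linear", "sigmoid")) {
    s <- make_schedule(kind, T = 100)
    oracle <- make_oracle_predictor(y0, s)
    for (start_t in c(1L, 7L, 40L, 100L)) {
      yt <- forward_sample(y0, start_t, s, seed = start_t)
      for (variance in c("sqrt_one_minus_abar", "beta_tilde")) {
        rec <- reverse_denoise(oracle, s, y_start = yt, start_t = start_t,
          stochastic = FALSE, variance = variance)
        expect_lt(max(abs(rec - y0)), 1e-6)
      }
    }
  }
})

test_that("the zero predictor maps a zero latent to zero", {
  s <- make_schedule("linear", T = 20)
  out <- reverse_denoise(zero_predictor, s, y_start = matrix(0, 4, 4),
    start_t = 20, stochastic = FALSE)
  expect_equal(out, matrix(0, 4, 4))
})

test_that("reverse chains are seed-reproducible and genuinely stochastic", {
  s <- make_schedule("linear", T = 30)
  pred <- function(y, t, x = NULL) 0.1 * y
  y_start <- matrix(rnorm(16), 4)
  a <- reverse_denoise(pred, s, y_start = y_start, start_t = 30,
    stochastic = TRUE, seed = 42)
  b <- reverse_denoise(pred, s, y_start = y_start, start_t = 30,
    stochastic = TRUE, seed = 42)
  c <- reverse_denoise(pred, s, y_start = y_start, start_t = 30,
    stochastic = TRUE, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("conditional and unconditional chains agree when x is ignored", {
  s <- make_schedule("linear", T = 25)
  pred_ignores_x <- function(y, t, x = NULL) 0.05 * y
  y_start <- matrix(rnorm(36), 6)
  a <- reverse_denoise(pred_ignores_x, s, y_start = y_start, start_t = 25,
    stochastic = FALSE)
  b <- reverse_denoise(pred_ignores_x, s, x = matrix(5, 6, 6),
    y_start = y_start, start_t = 25, stochastic = FALSE)
  expect_identical(a, b)
})

test_that("match_start_time finds the SNR-matched step", {
  s <- make_schedule("linear", T = 1000)
  expect_equal(match_start_time(1e-12, s), 1L)
  # linear-scan oracle
  ratio <- sqrt((1 - s$alpha_bar) / s$alpha_bar)
  scan <- function(sx) { for (t in 1:1000) if (ratio[t] >= sx) return(t); 1000L }
  for (sx in c(0.05, 0.1, 0.5, 1, 10)) {
    expect_equal(match_start_time(sx, s), scan(sx))
  }
  # a short, mild schedule whose terminal noise-to-signal ratio is tiny
  s_short <- make_schedule("linear", T = 5, beta_start = 1e-4,
    beta_end = 2e-4)
  expect_warning(t_sat <- match_start_time(0.5, s_short), "exceeds")
  expect_equal(t_sat, 5L)
})
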