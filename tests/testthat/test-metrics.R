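test_that("mse matches a brute-force double loop", {
  a <- random_unit_map(15, 1)
  b <- random_unit_map(15, 2)
  expect_identical(mse_map(a, a), 0)
  expect_equal(mse_map(matrix(0, 4, 4), matrix(0.1, 4, 4)), 0.01)
  loop <- 0
  for (i in 1:15) for (j in 1:15) loop <- loop + (a[i, j] - b[i, j])^2
  expect_equal(mse_map(a, b), loop / 225, tolerance = 1e-12)
  expect_error(mse_map(a, matrix(0, 3, 3)), class = "hicdiffuse_shape_error")
})

test_that("psnr follows its closed form", {
  a <- matrix(0, 5, 5); b <- matrix(0.1, 5, 5)     # mse = 0.01
  expect_equal(psnr_map(a, b), 20)
  expect_identical(psnr_map(a, a), Inf)
  expect_equal(psnr_map(a, b, data_range = 2) - psnr_map(a, b),
    20 * log10(2))
  expect_error(psnr_map(a, b, data_range = 0), class = "hicdiffuse_range_error")
})

test_that("psnr strictly decreases as noise grows", {
  set.seed(9)
  clean <- random_unit_map(32, 5)
  vals <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5), function(s) {
    noisy <- pmin(pmax(clean + matrix(rnorm(1024, sd = s), 32), 0), 1)
    psnr_map(clean, noisy)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("snr is the reference power over residual power", {
  expect_identical(snr_map(matrix(1, 3, 3), matrix(1, 3, 3)), Inf)
  expect_equal(snr_map(matrix(1, 7, 7), matrix(0.9, 7, 7)), 100)
  a <- random_unit_map(12, 3); b <- random_unit_map(12, 4)
  num <- 0; den <- 0
  for (i in 1:12) for (j in 1:12) {
    num <- num + a[i, j]^2
    den <- den + (a[i, j] - b[i, j])^2
  }
  expect_equal(snr_map(a, b), num / den, tolerance = 1e-9)
})

test_that("ssim equals 1 on identity, the luminance form on constants, and is negative on inverted structure", {
  a <- random_unit_map(30, 7)
  expect_equal(ssim_map(a, a), 1)

  ca <- matrix(0.2, 24, 24); cb <- matrix(0.3, 24, 24)
  C1 <- 0.01^2
  expect_equal(ssim_map(ca, cb),
    (2 * 0.2 * 0.3 + C1) / (0.2^2 + 0.3^2 + C1), tolerance = 1e-12)

  checker <- outer(1:24, 1:24, function(i, j) (i + j) %% 2)
  expect_lt(ssim_map(checker, 1 - checker), 0)
  expect_error(ssim_map(a - 1, a), class = "hicdiffuse_range_error")
})

test_that("ssim reproduces the reference implementation on a frozen fixture", {
  # expected value computed with scikit-image structural_similarity
  # (gaussian_weights = TRUE, sigma = 1.5, use_sample_covariance = FALSE,
  # data_range = 1) on the identical matrices
  set.seed(11)
  a <- matrix(runif(40 * 40), 40)
  b <- pmin(pmax(a + rnorm(1600, sd = 0.1), 0), 1)
  expect_equal(ssim_map(a, b), 0.9469331552, tolerance = 1e-8)
})

test_that("hicrep scc is 1 on self and affine-rescaled copies", {
  a <- random_unit_map(20, 12)
  expect_equal(hicrep_scc(a, a, h = 1, max_dist_bins = 10), 1)
  expect_equal(hicrep_scc(a, 2.5 * a + 0.2, h = 1, max_dist_bins = 10), 1,
    tolerance = 1e-12)
  expect_warning(
    val <- hicrep_scc(matrix(1, 6, 6), matrix(1, 6, 6), h = 0,
      max_dist_bins = 3),
    "degenerate")
  expect_true(is.na(val))
})

test_that("hicrep scc matches the brute-force stratified oracle", {
  a <- random_unit_map(20, 21)
  b <- random_unit_map(20, 22)
  expect_equal(hicrep_scc(a, b, h = 1, max_dist_bins = 10),
    oracle_scc(a, b, h = 1, max_dist = 10), tolerance = 1e-10)
  expect_equal(hicrep_scc(a, b, h = 0, max_dist_bins = 5),
    oracle_scc(a, b, h = 0, max_dist = 5), tolerance = 1e-10)
})

test_that("hicrep reduces to plain Pearson on a single live stratum", {
  set.seed(13)
  a <- matrix(runif(100), 10); a <- (a + t(a)) / 2
  b <- matrix(runif(100), 10); b <- (b + t(b)) / 2
  diag(a) <- 0.5; diag(b) <- 0.5       # degenerate d = 0 stratum is skipped
  i <- 1:9
  expect_equal(hicrep_scc(a, b, h = 0, max_dist_bins = 1),
    cor(a[cbind(i, i + 1)], b[cbind(i, i + 1)]), tolerance = 1e-12)
})

test_that("insulation vectors flag uniformity and planted boundaries", {
  expect_equal(unname(insulation_vector(matrix(0.4, 30, 30), 5)),
    rep(0, 20))
  # two TADs, no inter-block contact: the minimum sits at the boundary
  m <- matrix(0, 20, 20)
  m[1:10, 1:10] <- 1
  m[11:20, 11:20] <- 1
  iv <- insulation_vector(m, 3)
  expect_equal(as.integer(names(iv)[which.min(iv)]), 10L, tolerance = 1)
  expect_error(insulation_vector(matrix(0, 10, 10), 5),
    class = "hicdiffuse_range_error")
})

test_that("insulation L2 matches the loop oracle and vanishes on identity", {
  a <- random_unit_map(30, 31)
  b <- random_unit_map(30, 32)
  expect_identical(insulation_l2(a, a, 5), 0)
  v1 <- insulation_vector(a, 5)
  v2 <- insulation_vector(b, 5)
  loop <- 0
  for (k in seq_along(v1)) loop <- loop + (v1[k] - v2[k])^2
  expect_equal(insulation_l2(a, b, 5), sqrt(unname(loop)), tolerance = 1e-9)
})

test_that("evaluate_maps renormalizes model-range input and reports all six metrics", {
  set.seed(14)
  y0 <- matrix(runif(900, -1, 1), 30)
  rep1 <- evaluate_maps(y0, y0, space = "model")
  expect_named(rep1, c("psnr", "ssim", "mse", "snr", "hicrep",
    "insulation_l2"))
  expect_identical(rep1$mse, 0)
  expect_identical(rep1$psnr, Inf)
  expect_equal(rep1$ssim, 1)
  expect_equal(rep1$hicrep, 1)
  expect_identical(rep1$insulation_l2, 0)
  # out-of-range estimates are clipped before scoring, so ssim is defined
  noisy <- y0 + matrix(rnorm(900, sd = 0.5), 30)
  rep2 <- evaluate_maps(y0, noisy, space = "model")
  expect_true(all(is.finite(unlist(rep2))))
  expect_lt(rep2$ssim, 1)
})
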