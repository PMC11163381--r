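test_that("COO pixel tables fill the matrix symmetrically from the upper triangle", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tbin1\tbin2\tcount",
    "chr1\t0\t1\t5",
    "chr1\t1\t2\t2"
  ), path)
  cm <- read_contact_map(path, chrom = "chr1", resolution = 40000)
  expect_equal(cm$n_bins, 3L)
  expect_equal(cm$values[1, 2], 5)
  expect_equal(cm$values[2, 1], 5)
  expect_equal(cm$values[2, 3], 2)
  expect_equal(diag(cm$values), rep(0, 3))
  expect_true(cm$symmetric)
})

test_that("unknown chromosome errors name the available ones", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tbin1\tbin2\tcount", "chr1\t0\t1\t5", "chr2\t0\t0\t3"),
    path)
  expect_error(read_contact_map(path, chrom = "chrZZ"),
    "chr1.*chr2", class = "hicdiffuse_chrom_error")
})

test_that("dense, COO and MatrixMarket round-trips reproduce the matrix exactly", {
  m <- generate_map(synthetic_params(n_bins = 20L, seed = 5))
  for (fmt in c("dense", "coo", "mtx")) {
    path <- withr::local_tempfile(fileext = switch(fmt, coo = ".tsv",
      mtx = ".mtx", ".txt"))
    write_contact_map(m, path, format = fmt)
    back <- read_contact_map(path, chrom = m$chrom, n_bins = 20L)
    expect_equal(back$values, m$values, tolerance = 0,
      info = paste("format", fmt))
  }
})

test_that("non-square dense input raises a dimension error", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3", "4 5 6"), path)
  expect_error(read_contact_map(path), "square",
    class = "hicdiffuse_shape_error")
})

test_that("normalize_unit clips at the requested quantile and divides", {
  m <- matrix(c(0, 10, 10, 0), 2)
  u <- normalize_unit(m, clip_quantile = 1)
  expect_equal(max(u), 1)
  expect_equal(unclass(u), m / 10, ignore_attr = TRUE)

  zero <- normalize_unit(matrix(0, 4, 4))
  expect_equal(unclass(zero), matrix(0, 4, 4), ignore_attr = TRUE)
  expect_equal(attr(zero, "clip_value"), 1)

  # outlier maps to exactly 1 when clipped below it; clip value equals the
  # direct quantile of the flattened nonzero entries
  set.seed(3)
  m2 <- matrix(rexp(400) + 0.01, 20)
  m2[5, 7] <- 1e4
  u2 <- normalize_unit(m2, clip_quantile = 0.999)
  expect_equal(attr(u2, "clip_value"),
    unname(quantile(m2[m2 > 0], 0.999)))
  expect_equal(u2[5, 7], 1)
  expect_true(all(u2 >= 0 & u2 <= 1))
})

test_that("normalize_unit is scale-equivariant", {
  set.seed(4)
  m <- matrix(rpois(100, 3), 10)
  u1 <- normalize_unit(m, 0.99)
  for (c in c(0.5, 7, 1234.5)) {
    expect_equal(unclass(normalize_unit(c * m, 0.99)), unclass(u1),
      tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("model-range scaling is 2u - 1 with an exact inverse", {
  u <- matrix(c(0, 1, 0.5, 0.25), 2)
  y <- to_model_range(u)
  expect_equal(unclass(y), matrix(c(-1, 1, 0, -0.5), 2), ignore_attr = TRUE)
  expect_equal(unclass(to_model_range(matrix(0.25, 3, 3))),
    matrix(-0.5, 3, 3), ignore_attr = TRUE)
  expect_equal(unclass(from_model_range(y, clip = FALSE)), unclass(u),
    tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(to_model_range(matrix(1.5, 2, 2)),
    class = "hicdiffuse_range_error")
})

test_that("from_model_range maps endpoints and clips on request", {
  expect_equal(unclass(from_model_range(matrix(c(-1, 1), 1))),
    matrix(c(0, 1), 1), ignore_attr = TRUE)
  expect_equal(unclass(from_model_range(matrix(-1.2, 1), clip = TRUE))[1], 0)
  expect_equal(unclass(from_model_range(matrix(-1.2, 1), clip = FALSE))[1],
    -0.1)
})

test_that("contact_map records asymmetry instead of assuming it away", {
  m <- matrix(c(0, 1, 2, 0), 2)
  cm <- contact_map(m, "chr1", 40000)
  expect_false(cm$symmetric)
  expect_error(contact_map(matrix(-1, 2, 2)), class = "hicdiffuse_range_error")
  expect_error(contact_map(matrix(0, 2, 3)), class = "hicdiffuse_shape_error")
})

test_that("tidy.contact_map returns the upper triangle with genomic starts", {
  m <- matrix(c(1, 2, 2, 3), 2)
  td <- tidy(contact_map(m, "chr9", 10000))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3L)
  expect_equal(td$start2[td$bin1 == 0 & td$bin2 == 1], 10000)
})
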