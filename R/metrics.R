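# Evaluation metrics, computed on [0, 1]-renormalized matrices.

#' Mean squared error between two maps
#'
#' @param a,b Same-shape matrices on the `[0, 1]` scale.
#' @return Mean of squared entrywise differences.
#' @export
mse_map <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  assert_same_shape(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(data_range^2 / mse)`; identical inputs give `Inf`.
#'
#' @inheritParams mse_map
#' @param data_range Dynamic range of the data (1 for unit-scaled maps).
#' @export
psnr_map <- function(a, b, data_range = 1) {
  if (data_range <= 0) abort("`data_range` must be > 0.",
    class = "hicdiffuse_range_error")
  m <- mse_map(a, b)
  if (m == 0) return(Inf)
  10 * log10(data_range^2 / m)
}

#' Signal-to-noise power ratio
#'
#' `sum(target^2) / sum((target - estimate)^2)`, a linear power ratio (not
#' dB). Asymmetric: the first argument is the reference signal. Zero
#' residual gives `Inf`.
#'
#' @param target Reference map on the `[0, 1]` scale.
#' @param estimate Estimate to score.
#' @export
snr_map <- function(target, estimate) {
  target <- unclass(target); estimate <- unclass(estimate)
  assert_same_shape(target, estimate)
  denom <- sum((target - estimate)^2)
  if (denom == 0) return(Inf)
  sum(target^2) / denom
}

# Gaussian filter with reflected edges, matching the usual SSIM reference
# implementation (11-tap kernel, sigma 1.5).
gaussian_filter2 <- function(x, sigma = 1.5, radius = 5L) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  idx_r <- c(rev(seq_len(radius)), seq_len(n), n - seq_len(radius) + 1L)
  idx_c <- c(rev(seq_len(radius)), seq_len(m), m - seq_len(radius) + 1L)
  xp <- x[idx_r, idx_c, drop = FALSE]
  # separable convolution: rows then columns
  out <- matrix(0, n, m + 2L * radius)
  for (j in seq_along(k)) out <- out + k[j] * xp[j:(j + n - 1L), , drop = FALSE]
  res <- matrix(0, n, m)
  for (j in seq_along(k)) res <- res + k[j] * out[, j:(j + m - 1L), drop = FALSE]
  res
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5), stabilizers
#' `K1 = 0.01`, `K2 = 0.03` and data range 1 — the standard reference
#' settings. Local statistics use Gaussian-weighted moments; a border of
#' half the window width is cropped from the SSIM map before averaging to
#' avoid edge effects. Inputs must be non-negative (renormalize model-range
#' data with [from_model_range()] first).
#'
#' @inheritParams mse_map
#' @param data_range Dynamic range (1 for unit-scaled maps).
#' @export
ssim_map <- function(a, b, data_range = 1) {
  a <- unclass(a); b <- unclass(b)
  assert_same_shape(a, b)
  if (any(a < 0) || any(b < 0)) {
    abort("ssim_map() expects non-negative entries.",
      class = "hicdiffuse_range_error")
  }
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_a <- gaussian_filter2(a); mu_b <- gaussian_filter2(b)
  va <- gaussian_filter2(a * a) - mu_a^2
  vb <- gaussian_filter2(b * b) - mu_b^2
  cab <- gaussian_filter2(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  r <- 5L
  n <- nrow(s); m <- ncol(s)
  if (n > 2L * r && m > 2L * r) s <- s[(r + 1L):(n - r), (r + 1L):(m - r)]
  mean(s)
}

# (2h+1)^2 moving-average smoother with edge truncation (mean over the
# in-bounds neighbourhood), the HiCRep pre-smoothing step.
mean_filter2 <- function(x, h) {
  if (h == 0L) return(x)
  n <- nrow(x); m <- ncol(x)
  acc <- matrix(0, n, m); cnt <- matrix(0, n, m)
  for (di in -h:h) {
    ri <- intersect(seq_len(n), seq_len(n) + di)
    for (dj in -h:h) {
      cj <- intersect(seq_len(m), seq_len(m) + dj)
      acc[ri - di, cj - dj] <- acc[ri - di, cj - dj] + x[ri, cj]
      cnt[ri - di, cj - dj] <- cnt[ri - di, cj - dj] + 1
    }
  }
  acc / cnt
}

#' HiCRep stratum-adjusted correlation coefficient (SCC)
#'
#' Both maps are smoothed with a `(2h+1) x (2h+1)` mean filter, entries are
#' stratified by diagonal distance `d = 0..max_dist_bins`, and the SCC is
#' the weighted average of the per-stratum Pearson correlations with weights
#' `N_d * r1_d * r2_d` (stratum size times the two stratum standard
#' deviations). Strata with zero variance in either map are skipped;
#' identical maps score 1 and the score is invariant to per-map affine
#' rescaling `c * a + k` (c > 0).
#'
#' @param a,b Same-shape non-negative matrices.
#' @param h Smoothing half-width (0 disables smoothing).
#' @param max_dist_bins Largest diagonal distance included (bins); defaults
#'   to 5 Mb worth of 40 kb bins, capped at `n - 2`.
#' @return SCC in `[-1, 1]`, or `NA` with a warning if every stratum is
#'   degenerate.
#' @export
hicrep_scc <- function(a, b, h = 1L, max_dist_bins = NULL) {
  a <- unclass(a); b <- unclass(b)
  assert_same_shape(a, b)
  if (any(a < 0) || any(b < 0)) {
    abort("hicrep_scc() expects non-negative entries.",
      class = "hicdiffuse_range_error")
  }
  n <- nrow(a)
  max_dist_bins <- min(max_dist_bins %||% 125L, n - 2L)
  if (h < 0 || max_dist_bins < 1) {
    abort("`h` must be >= 0 and `max_dist_bins` >= 1.",
      class = "hicdiffuse_range_error")
  }
  as <- mean_filter2(a, as.integer(h))
  bs <- mean_filter2(b, as.integer(h))
  num <- 0; den <- 0; any_ok <- FALSE
  for (d in 0:max_dist_bins) {
    i <- seq_len(n - d)
    va <- as[cbind(i, i + d)]
    vb <- bs[cbind(i, i + d)]
    if (length(va) < 2L) next
    sa <- sd(va); sb <- sd(vb)
    if (sa == 0 || sb == 0) next
    rho <- cor(va, vb)
    w <- length(va) * sa * sb
    num <- num + w * rho
    den <- den + w
    any_ok <- TRUE
  }
  if (!any_ok) {
    warn("all distance strata are degenerate; SCC undefined.")
    return(NA_real_)
  }
  num / den
}

#' TAD insulation score vector
#'
#' For every bin `i` far enough from the edges, the mean contact count in
#' the `(w+1) x (w+1)` diamond window spanning rows `i-w..i` and columns
#' `i..i+w` (the window crossing the diagonal at `i`). The vector is
#' log2-normalized by its own mean with a pseudo-count, so a uniform matrix
#' maps to all zeros and local minima mark insulation (TAD) boundaries.
#'
#' @param m Square matrix on the `[0, 1]` (or count) scale.
#' @param window_bins Window half-width `w` in bins.
#' @param pseudo_count Stabilizer for the log-ratio.
#' @return Numeric vector of length `n - 2 * window_bins`, named by 0-based
#'   bin index.
#' @export
insulation_vector <- function(m, window_bins = 10L, pseudo_count = 1e-9) {
  v <- unclass(m)
  n <- nrow(v)
  w <- as.integer(window_bins)
  if (w < 1) abort("`window_bins` must be >= 1.", class = "hicdiffuse_range_error")
  if (n <= 2L * w) {
    abort(sprintf("matrix side %d too small for window %d.", n, w),
      class = "hicdiffuse_range_error")
  }
  bins <- (w + 1L):(n - w)
  raw <- vapply(bins, function(i) {
    mean(v[(i - w):i, i:(i + w)])
  }, numeric(1))
  out <- log2((raw + pseudo_count) / (mean(raw) + pseudo_count))
  names(out) <- bins - 1L
  out
}

#' Insulation-profile L2 dissimilarity
#'
#' Euclidean norm of the difference between the insulation score vectors of
#' a reference map and a denoised map; 0 means the TAD insulation structure
#' is perfectly preserved, and smaller is better.
#'
#' @param clean Reference map.
#' @param denoised Map to score.
#' @param window_bins Insulation window half-width, see
#'   [insulation_vector()].
#' @export
insulation_l2 <- function(clean, denoised, window_bins = 10L) {
  assert_same_shape(unclass(clean), unclass(denoised))
  v1 <- insulation_vector(clean, window_bins)
  v2 <- insulation_vector(denoised, window_bins)
  sqrt(sum((v1 - v2)^2))
}

#' Full metric report for a denoised map
#'
#' Computes all six scores (PSNR, SSIM, MSE, SNR, HiCRep SCC, insulation
#' L2) of an estimate against a clean reference. Model-range inputs
#' (`space = "model"`) are first renormalized to `[0, 1]` with clipping, the
#' scale every metric is defined on.
#'
#' @param clean Reference map (clean ground truth).
#' @param estimate Denoised or noisy map to score.
#' @param space `"model"` if inputs are on `[-1, 1]`, `"unit"` if already on
#'   `[0, 1]`.
#' @param hicrep_h,max_dist_bins,insulation_window Metric settings, see the
#'   individual metric functions.
#' @return A one-row tibble with columns `psnr`, `ssim`, `mse`, `snr`,
#'   `hicrep`, `insulation_l2`.
#' @export
evaluate_maps <- function(clean, estimate, space = c("model", "unit"),
                          hicrep_h = 1L, max_dist_bins = NULL,
                          insulation_window = 10L) {
  space <- match.arg(space)
  if (space == "model") {
    clean <- from_model_range(clean, clip = TRUE)
    estimate <- from_model_range(estimate, clip = TRUE)
  }
  tibble::tibble(
    psnr = psnr_map(clean, estimate),
    ssim = ssim_map(clean, estimate),
    mse = mse_map(clean, estimate),
    snr = snr_map(clean, estimate),
    hicrep = hicrep_scc(clean, estimate, h = hicrep_h,
      max_dist_bins = max_dist_bins),
    insulation_l2 = insulation_l2(clean, estimate,
      window_bins = insulation_window)
  )
}
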