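# Shared fixtures and independent oracle implementations used across tests.

# Oracle noise predictor: knows the clean map and returns the noise actually
# embedded in the latent at step t, eps = (y - sqrt(abar_t) y0) / sqrt(1 - abar_t).
make_oracle_predictor <- function(y0, sched) {
  y0 <- unclass(y0)
  function(y, t, x = NULL) {
    ab <- sched$alpha_bar[t]
    (unclass(y) - sqrt(ab) * y0) / sqrt(1 - ab)
  }
}

zero_predictor <- function(y, t, x = NULL) unclass(y) * 0

# Brute-force HiCRep SCC: materializes every stratum of the smoothed
# matrices and averages the per-stratum Pearson correlations with weights
# N_d * sd1_d * sd2_d. Smoothing by explicit double loop (independent of the
# package's shift-based filter).
oracle_scc <- function(a, b, h, max_dist) {
  smooth_loop <- function(x) {
    n <- nrow(x)
    out <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      ri <- max(1, i - h):min(n, i + h)
      cj <- max(1, j - h):min(n, j + h)
      out[i, j] <- mean(x[ri, cj])
    }
    out
  }
  as <- smooth_loop(a); bs <- smooth_loop(b)
  n <- nrow(a)
  num <- 0; den <- 0
  for (d in 0:max_dist) {
    va <- numeric(0); vb <- numeric(0)
    for (i in seq_len(n - d)) {
      va <- c(va, as[i, i + d]); vb <- c(vb, bs[i, i + d])
    }
    if (length(va) < 2) next
    if (sd(va) == 0 || sd(vb) == 0) next
    w <- length(va) * sd(va) * sd(vb)
    num <- num + w * cor(va, vb)
    den <- den + w
  }
  num / den
}

# A small symmetric non-negative random map on [0, 1].
random_unit_map <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n), n)
  (m + t(m)) / 2
}

# Tiny predictor builds used by several files (fast to construct).
tiny_residual <- function(mode = "unconditional", seed = 1) {
  build_residual_predictor(channels = 8L, n_blocks = 2L, mode = mode,
    time_dim = 16L, seed = seed)
}

tiny_unet <- function(mode = "unconditional", seed = 1) {
  build_unet_predictor(base_channels = 8L, depth = 2L, mode = mode,
    n_heads = 2L, time_dim = 16L, seed = seed)
}
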