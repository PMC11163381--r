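#' Build a noise variance schedule
#'
#' The forward process adds Gaussian noise with per-step variance `beta_t`;
#' `alpha_t = 1 - beta_t` and `abar_t = prod(alpha_1..alpha_t)` is the
#' cumulative signal retention, so `y_t ~ N(sqrt(abar_t) y0, (1 - abar_t) I)`.
#' Two shapes are supported: `linear` (beta evenly spaced between the bounds)
#' and `sigmoid` (beta following a logistic ramp, slow at both ends), the two
#' variants compared in the schedule ablation.
#'
#' @param kind `"linear"` or `"sigmoid"`.
#' @param T Number of diffusion steps (>= 1).
#' @param beta_start,beta_end Schedule bounds, `0 < beta_start <= beta_end < 1`.
#'   Defaults are the classic DDPM choices `1e-4` and `0.02`.
#' @return A `noise_schedule` with vectors `beta`, `alpha`, `alpha_bar`,
#'   `sigma_tilde` (= `sqrt(1 - alpha_bar)`) indexed by `t = 1..T`.
#' @examples
#' sched <- make_schedule("linear", T = 2, beta_start = 0.1, beta_end = 0.2)
#' sched$alpha_bar  # 0.9, 0.72
#' @export
make_schedule <- function(kind = c("linear", "sigmoid"), T = 1000L,
                          beta_start = 1e-4, beta_end = 0.02) {
  kind <- match.arg(kind)
  if (T < 1) abort("`T` must be >= 1.", class = "hicdiffuse_range_error")
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    abort("need 0 < beta_start <= beta_end < 1.", class = "hicdiffuse_range_error")
  }
  beta <- switch(kind,
    linear = if (T == 1L) beta_start else seq(beta_start, beta_end, length.out = T),
    sigmoid = {
      # logistic ramp on logits in [-6, 6]; plogis is the logistic function
      l <- if (T == 1L) 0 else seq(-6, 6, length.out = T)
      beta_start + (beta_end - beta_start) * stats::plogis(l)
    }
  )
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  structure(
    list(
      kind = kind, T = as.integer(T), beta = beta, alpha = alpha,
      alpha_bar = alpha_bar, sigma_tilde = sqrt(1 - alpha_bar)
    ),
    class = "noise_schedule"
  )
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf(
    "<noise_schedule> %s, T = %d, beta in [%g, %g], alpha_bar_T = %.4g\n",
    x$kind, x$T, min(x$beta), max(x$beta), x$alpha_bar[x$T]
  ))
  invisible(x)
}

#' @export
tidy.noise_schedule <- function(x, ...) {
  tibble::tibble(
    t = seq_len(x$T), beta = x$beta, alpha = x$alpha,
    alpha_bar = x$alpha_bar, sigma_tilde = x$sigma_tilde
  )
}

#' @export
autoplot.noise_schedule <- function(object, ...) {
  df <- tidy(object)
  long <- tibble::tibble(
    t = rep(df$t, 2),
    value = c(df$beta, df$alpha_bar),
    quantity = rep(c("beta", "alpha_bar"), each = nrow(df))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
      colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "diffusion step t", y = NULL) +
    ggplot2::theme_minimal()
}

check_t <- function(t, sched) {
  if (t < 1 || t > sched$T) {
    abort(sprintf("t = %d outside [1, %d].", t, sched$T),
      class = "hicdiffuse_range_error")
  }
  as.integer(t)
}

#' Sample the forward process at time t
#'
#' Draws from the closed-form marginal
#' `y_t = sqrt(abar_t) * y0 + sqrt(1 - abar_t) * eps` with `eps ~ N(0, I)`,
#' which equals composing the one-step kernels `q(y_t | y_{t-1})`.
#'
#' @param y0 Clean matrix/array in model range.
#' @param t Diffusion step in `[1, T]`.
#' @param sched A [make_schedule()] object.
#' @param eps Optional noise field of the same shape (supply for oracle
#'   computations); drawn internally when `NULL`.
#' @param seed Optional seed for the internal draw.
#' @return `y_t`, same shape as `y0`.
#' @export
forward_sample <- function(y0, t, sched, eps = NULL, seed = NULL) {
  t <- check_t(t, sched)
  v <- unclass(y0)
  if (is.null(eps)) {
    eps <- with_seed(seed, array(rnorm(length(v)), dim = dim(v) %||% length(v)))
  } else if (length(eps) != length(v)) {
    abort("`eps` must have the same shape as `y0`.",
      class = "hicdiffuse_shape_error")
  }
  ab <- sched$alpha_bar[t]
  sqrt(ab) * v + sqrt(1 - ab) * unclass(eps)
}

#' Posterior parameters of one reverse step
#'
#' Given the latent `y_t` and the predicted noise, the reverse-step mean is
#' `mu = (y_t - (beta_t / sqrt(1 - abar_t)) * eps_hat) / sqrt(alpha_t)` (the
#' standard DDPM parameterization, the one consistent with the
#' `||eps - f(y_t, t)||^2` training objective). The step standard deviation
#' defaults to `sqrt(1 - abar_{t-1})` (with `abar_0 := 1`, so the final step
#' is noiseless); the conventional posterior variance
#' `beta_t (1 - abar_{t-1}) / (1 - abar_t)` is selectable via
#' `variance = "beta_tilde"`.
#'
#' @param y_next Latent `y_t` (matrix or array).
#' @param eps_hat Predicted noise, same shape.
#' @param t_next The step `t` being inverted, in `[1, T]`.
#' @param sched A [make_schedule()] object.
#' @param variance `"sqrt_one_minus_abar"` (default) or `"beta_tilde"`.
#' @return List with `mu` (same shape) and scalar `sigma >= 0`.
#' @export
posterior_mean <- function(y_next, eps_hat, t_next, sched,
                           variance = c("sqrt_one_minus_abar", "beta_tilde")) {
  variance <- match.arg(variance)
  t_next <- check_t(t_next, sched)
  yv <- unclass(y_next); ev <- unclass(eps_hat)
  if (length(yv) != length(ev)) {
    abort("`eps_hat` must match the shape of `y_next`.",
      class = "hicdiffuse_shape_error")
  }
  ab_t <- sched$alpha_bar[t_next]
  ab_prev <- if (t_next == 1L) 1 else sched$alpha_bar[t_next - 1L]
  beta_t <- sched$beta[t_next]
  mu <- (yv - (beta_t / sqrt(1 - ab_t)) * ev) / sqrt(sched$alpha[t_next])
  sigma <- switch(variance,
    sqrt_one_minus_abar = sqrt(1 - ab_prev),
    beta_tilde = sqrt(beta_t * (1 - ab_prev) / (1 - ab_t))
  )
  list(mu = mu, sigma = sigma)
}

#' Match an observation's noise level to a diffusion step
#'
#' A noisy observation `x = y0 + sigma_x * Z` can be aligned with the forward
#' trajectory: scaling by `sqrt(abar_t)` gives
#' `sqrt(abar_t) x = sqrt(abar_t) y0 + sqrt(abar_t) sigma_x Z`, which matches
#' the marginal of `y_t` when `sqrt((1 - abar_t)/abar_t) = sigma_x`. The
#' smallest `t` whose noise-to-signal ratio reaches `sigma_x` is returned, so
#' the unconditional reverse chain can start from the scaled observation
#' instead of pure noise.
#'
#' @param sigma_x Observation noise level (> 0).
#' @param sched A [make_schedule()] object.
#' @return Integer step; if `sigma_x` exceeds the schedule's terminal
#'   noise-to-signal ratio, `T` with a warning.
#' @export
match_start_time <- function(sigma_x, sched) {
  if (sigma_x <= 0) return(1L)
  ratio <- sqrt((1 - sched$alpha_bar) / sched$alpha_bar)
  t <- which(ratio >= sigma_x)[1]
  if (is.na(t)) {
    warn(sprintf(
      "sigma_x = %g exceeds the schedule's terminal noise-to-signal ratio %.4g; using t = T.",
      sigma_x, ratio[sched$T]
    ))
    return(sched$T)
  }
  as.integer(t)
}

# Call a noise predictor (built backbone or plain function) on a latent.
call_predictor <- function(predictor, y, t, x = NULL) {
  eps_hat <- if (is.function(predictor)) {
    predictor(y, t, x)
  } else {
    predict_noise(predictor, y, t, x = x)
  }
  if (length(eps_hat) != length(y)) {
    abort("predictor output shape does not match its input.",
      class = "hicdiffuse_shape_error")
  }
  eps_hat
}

#' Run the reverse denoising chain
#'
#' Iterates `t = start_t, ..., 1`: predict the noise in the current latent,
#' form the posterior mean and standard deviation with [posterior_mean()],
#' and set `y_{t-1} = mu + sigma * z` with `z ~ N(0, I)` (`z = 0` when
#' `stochastic = FALSE`). Conditional predictors receive the observation `x`
#' at every step; unconditional chains may still use `x` purely to seed the
#' start point via [match_start_time()] scaling (see `y_start`).
#'
#' @param predictor A built noise predictor (see
#'   [build_residual_predictor()]) or a function `f(y, t, x)` returning a
#'   same-shape noise estimate.
#' @param sched A [make_schedule()] object.
#' @param x Observation passed to conditional predictors (or `NULL`).
#' @param start_t First step of the chain (`<= T`).
#' @param y_start Starting latent `y_{start_t}`. If `NULL`, drawn `N(0, I)`
#'   with the shape of `x` (pure generation); one of `y_start`/`x` must be
#'   given to fix the shape.
#' @param stochastic Sample the per-step Gaussian (TRUE) or take the mean
#'   path (FALSE)?
#' @param seed Optional seed; the chain is bit-reproducible given it.
#' @param variance Reverse-step variance variant, see [posterior_mean()].
#' @return The `y_0` estimate, same shape as the latent.
#' @export
reverse_denoise <- function(predictor, sched, x = NULL, start_t = sched$T,
                            y_start = NULL, stochastic = FALSE, seed = NULL,
                            variance = c("sqrt_one_minus_abar", "beta_tilde")) {
  variance <- match.arg(variance)
  start_t <- check_t(start_t, sched)
  if (is.null(y_start) && is.null(x)) {
    abort("supply `y_start` or `x` to fix the latent shape.",
      class = "hicdiffuse_shape_error")
  }
  with_seed(seed, {
    y <- if (!is.null(y_start)) {
      unclass(y_start)
    } else {
      array(rnorm(length(x)), dim = dim(x) %||% length(x))
    }
    for (t in rev(seq_len(start_t))) {
      eps_hat <- call_predictor(predictor, y, t, x)
      pp <- posterior_mean(y, eps_hat, t, sched, variance = variance)
      if (stochastic) {
        z <- array(rnorm(length(y)), dim = dim(y) %||% length(y))
        y <- pp$mu + pp$sigma * z
      } else {
        y <- pp$mu
      }
    }
    y
  })
}
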