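# Shared noise-predictor surface: both backbones implement the contract
# f_theta(y_t, t [, x]) -> eps_hat with identical spatial shape, where the
# conditional (supervised) variant concatenates the observation x as a second
# input channel, doubling the first convolution's input channels.

# ---- generic residual block --------------------------------------------
# conv 3x3 -> add per-channel time bias -> nonlinearity -> conv 3x3 -> + skip
# (1x1 projection on the skip path only when cin != cout).

resblock_init <- function(cin, cout, time_dim) {
  p <- list(
    conv1 = conv_init(3, 3, cin, cout),
    conv2 = conv_init(3, 3, cout, cout),
    tproj = dense_init(time_dim, cout)
  )
  if (cin != cout) p$skip <- list(w = matrix(rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout),
    b = numeric(cout))
  p
}

resblock_fwd <- function(x, p, th, act = c("relu", "silu")) {
  act <- match.arg(act)
  tb <- tproj_fwd(th, p$tproj)
  conv1_out <- conv3x3(x, p$conv1)
  a <- bias_act_fwd(conv1_out, tb, if (act == "relu") 0L else 1L)
  a2 <- conv3x3(a, p$conv2)
  skip <- if (!is.null(p$skip)) conv1x1(x, p$skip) else x
  list(out = skip + a2,
    cache = list(x = x, conv1_out = conv1_out, tb = tb, a = a, act = act))
}

resblock_bwd <- function(cache, p, th, gy) {
  g2 <- conv3x3_grad(cache$a, p$conv2, gy)
  ba <- bias_act_bwd(cache$conv1_out, cache$tb, g2$gx,
    if (cache$act == "relu") 0L else 1L)
  tp <- tproj_bwd(th, p$tproj, ba$gtb)
  g1 <- conv3x3_grad(cache$x, p$conv1, ba$gx)
  grads <- list(
    conv1 = list(w = g1$gw, b = g1$gb),
    conv2 = list(w = g2$gw, b = g2$gb),
    tproj = list(w = tp$gw, b = tp$gb)
  )
  gx <- g1$gx
  if (!is.null(p$skip)) {
    gs <- conv1x1_grad(cache$x, p$skip, gy)
    grads$skip <- list(w = gs$gw, b = gs$gb)
    gx <- gx + gs$gx
  } else {
    gx <- gx + gy
  }
  list(gx = gx, grads = grads, gh = tp$gh)
}

# ---- predictor surface --------------------------------------------------

new_noise_predictor <- function(backbone, mode, params, config) {
  structure(
    list(backbone = backbone, mode = mode, params = params, config = config),
    class = "noise_predictor"
  )
}

#' @export
print.noise_predictor <- function(x, ...) {
  cat(sprintf(
    "<noise_predictor> %s backbone, %s mode, %s parameters\n",
    x$backbone, x$mode, format(count_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

#' Count trainable parameters of a noise predictor
#'
#' @param p A built noise predictor.
#' @return Total number of scalar weights and biases.
#' @export
count_parameters <- function(p) {
  param_sum(p$params, length)
}

# Stack y (and x for conditional predictors) into the (H, W, C, B) input.
# y: matrix or (H, W, B) array; x must match when the predictor is conditional.
predictor_input <- function(p, y, x = NULL) {
  yv <- unclass(y)
  if (is.matrix(yv)) yv <- array(yv, c(dim(yv), 1L))
  d <- dim(yv)
  if (p$mode == "conditional") {
    if (is.null(x)) {
      abort("conditional predictor requires the observation `x`.",
        class = "hicdiffuse_config_error")
    }
    xv <- unclass(x)
    if (is.matrix(xv)) xv <- array(xv, c(dim(xv), 1L))
    if (!identical(dim(xv), d)) {
      abort("`x` must match the shape of `y`.", class = "hicdiffuse_shape_error")
    }
    arr <- array(0, c(d[1], d[2], 2L, d[3]))
    arr[, , 1L, ] <- yv
    arr[, , 2L, ] <- xv
  } else {
    arr <- array(yv, c(d[1], d[2], 1L, d[3]))
  }
  arr
}

predictor_forward <- function(p, input, t, train = FALSE) {
  switch(p$backbone,
    residual = resnet_forward(p, input, t, train = train),
    unet = unet_forward(p, input, t, train = train)
  )
}

predictor_backward <- function(p, cache, gout) {
  switch(p$backbone,
    residual = resnet_backward(p, cache, gout),
    unet = unet_backward(p, cache, gout)
  )
}

#' Predict the noise embedded in a latent
#'
#' Applies the trained (or freshly built) backbone to one tile or a batch of
#' tiles. This is the `f_theta(y_t, t[, x])` contract used by the training
#' losses and the reverse chain.
#'
#' @param p A noise predictor from [build_residual_predictor()] or
#'   [build_unet_predictor()].
#' @param y Latent: an `n x n` matrix or an `(n, n, B)` array of tiles.
#' @param t Integer time step, either a scalar (shared by the batch) or a
#'   length-`B` vector.
#' @param x Observation tile(s) for conditional predictors, same shape as `y`.
#' @return Noise estimate with the same shape as `y`.
#' @export
predict_noise <- function(p, y, t, x = NULL) {
  input <- predictor_input(p, y, x)
  B <- dim(input)[4]
  t <- if (length(t) == 1L) rep(as.numeric(t), B) else as.numeric(t)
  out <- predictor_forward(p, input, t, train = FALSE)$out
  res <- array(out, dim(input)[c(1, 2, 4)])
  if (is.matrix(unclass(y)) || length(dim(y)) == 2L) res <- res[, , 1L]
  res
}
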