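#' Build the deep residual noise predictor
#'
#' A head 3x3 convolution, `n_blocks` residual blocks (3x3 conv, additive
#' per-channel time bias, ReLU, 3x3 conv, identity skip), a global skip from
#' the head output to the tail input, and a tail 3x3 convolution back to one
#' data channel — the EDSR-style super-resolution lineage. The time step
#' enters through a sinusoidal embedding and a shared SiLU perceptron whose
#' output every block projects to a per-channel bias. The tail convolution is
#' zero-initialized so an untrained predictor outputs 0, which keeps the
#' first training steps well-scaled.
#'
#' In `conditional` mode the first convolution takes exactly twice the input
#' channels of the unconditional build: the latent `y_t` and the observation
#' `x` are channel-concatenated.
#'
#' @param channels Hidden width (channels per block). The full-scale
#'   configuration uses 64 channels and 32 blocks; scaled-down runs use
#'   32 channels and 4 blocks.
#' @param n_blocks Number of residual blocks.
#' @param mode `"unconditional"` or `"conditional"`.
#' @param time_dim Width of the sinusoidal time embedding.
#' @param seed Optional seed for weight initialization.
#' @return A `noise_predictor`.
#' @examples
#' p <- build_residual_predictor(channels = 8, n_blocks = 2, seed = 1)
#' eps_hat <- predict_noise(p, matrix(rnorm(64^2), 64), t = 10)
#' @export
build_residual_predictor <- function(channels = 64L, n_blocks = 32L,
                                     mode = c("unconditional", "conditional"),
                                     time_dim = 64L, seed = NULL) {
  mode <- match.arg(mode)
  if (channels < 1 || n_blocks < 1) {
    abort("`channels` and `n_blocks` must be >= 1.",
      class = "hicdiffuse_range_error")
  }
  cin <- if (mode == "conditional") 2L else 1L
  params <- with_seed(seed, {
    list(
      head = conv_init(3, 3, cin, channels),
      tmlp = list(w1 = dense_init(time_dim, time_dim)),
      blocks = lapply(seq_len(n_blocks), function(i) {
        resblock_init(channels, channels, time_dim)
      }),
      tail = conv_init(3, 3, channels, 1L, zero = TRUE)
    )
  })
  new_noise_predictor(
    "residual", mode, params,
    config = list(channels = as.integer(channels),
      n_blocks = as.integer(n_blocks), time_dim = as.integer(time_dim),
      in_channels = cin)
  )
}

# Forward/backward delegate the block stack to the fused float kernel
# (src/resnet.cpp); the time-embedding MLP and its projections stay in R.
resnet_forward <- function(p, input, t, train = FALSE) {
  pr <- p$params
  temb <- time_embedding(t, p$config$time_dim)
  tm <- time_mlp_fwd(temb, pr$tmlp)
  tbs <- lapply(pr$blocks, function(blk) tproj_fwd(tm$h, blk$tproj))
  weights <- list(
    head = pr$head,
    blocks = lapply(pr$blocks, function(blk) blk[c("conv1", "conv2")]),
    tail = pr$tail
  )
  fw <- resnet_fwd_cpp(input, weights, tbs, train)
  cache <- if (train) list(ws = fw$ws, weights = weights, tm = tm)
  list(out = fw$out, cache = cache)
}

resnet_backward <- function(p, cache, gout) {
  pr <- p$params
  bw <- resnet_bwd_cpp(cache$ws, cache$weights, gout)
  gh_time <- matrix(0, nrow(cache$tm$h), ncol(cache$tm$h))
  block_grads <- vector("list", length(pr$blocks))
  for (i in seq_along(pr$blocks)) {
    tp <- tproj_bwd(cache$tm$h, pr$blocks[[i]]$tproj, bw$blocks[[i]]$gtb)
    gh_time <- gh_time + tp$gh
    block_grads[[i]] <- list(
      conv1 = bw$blocks[[i]]$conv1,
      conv2 = bw$blocks[[i]]$conv2,
      tproj = list(w = tp$gw, b = tp$gb)
    )
  }
  grads <- list(
    head = bw$head,
    tmlp = time_mlp_bwd(cache$tm, pr$tmlp, gh_time),
    blocks = block_grads,
    tail = bw$tail
  )
  grads[names(pr)]
}
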