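#' Build the U-Net noise predictor
#'
#' The classic DDPM baseline: an encoder–decoder over 64x64 tiles with
#' channel width doubling at each of `depth` 2x downsamplings, skip
#' connections concatenated on the way up, SiLU residual blocks carrying the
#' sinusoidal time embedding, and multi-head self-attention inserted at the
#' requested resolution levels (level `depth`, the bottleneck, by default).
#' Same I/O contract as [build_residual_predictor()], including the doubled
#' input channels in conditional mode.
#'
#' @param base_channels Channel width at full resolution; level `l` uses
#'   `base_channels * 2^l`.
#' @param depth Number of downsamplings; the tile side (64) must be
#'   divisible by `2^depth`.
#' @param attention_levels Integer vector of levels (0 = full resolution,
#'   `depth` = bottleneck) that get a self-attention layer.
#' @param mode `"unconditional"` or `"conditional"`.
#' @param n_heads Attention heads; must divide the channel count at every
#'   attention level.
#' @param time_dim Width of the sinusoidal time embedding.
#' @param seed Optional seed for weight initialization.
#' @param tile_size Spatial input size the divisibility check is made for.
#' @return A `noise_predictor`.
#' @export
build_unet_predictor <- function(base_channels = 16L, depth = 2L,
                                 attention_levels = depth,
                                 mode = c("unconditional", "conditional"),
                                 n_heads = 4L, time_dim = 64L, seed = NULL,
                                 tile_size = 64L) {
  mode <- match.arg(mode)
  if (depth < 1 || tile_size %% (2^depth) != 0) {
    abort(sprintf("tile size %d is not divisible by 2^depth = %d.",
      tile_size, 2^depth), class = "hicdiffuse_range_error")
  }
  ch <- base_channels * 2^(0:depth)
  for (l in attention_levels) {
    if (l < 0 || l > depth) {
      abort("attention levels must lie in [0, depth].",
        class = "hicdiffuse_range_error")
    }
    if (ch[l + 1L] %% n_heads != 0) {
      abort(sprintf("channels at level %d (%d) not divisible by n_heads = %d.",
        l, ch[l + 1L], n_heads), class = "hicdiffuse_range_error")
    }
  }
  cin <- if (mode == "conditional") 2L else 1L
  params <- with_seed(seed, {
    enc <- vector("list", depth)
    dec <- vector("list", depth)
    drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
    for (l in seq_len(depth)) {           # encoder level l-1 (0-based)
      enc[[l]] <- drop_null(list(
        res = resblock_init(ch[l], ch[l], time_dim),
        att = if ((l - 1L) %in% attention_levels) attention_init(ch[l]),
        down = conv_init(3, 3, ch[l], ch[l + 1L])
      ))
      dec[[l]] <- drop_null(list(
        up = conv_init(3, 3, ch[l + 1L], ch[l]),
        res = resblock_init(2L * ch[l], ch[l], time_dim),
        att = if ((l - 1L) %in% attention_levels) attention_init(ch[l])
      ))
    }
    list(
      head = conv_init(3, 3, cin, ch[1L]),
      tmlp = list(w1 = dense_init(time_dim, time_dim)),
      enc = enc,
      mid1 = resblock_init(ch[depth + 1L], ch[depth + 1L], time_dim),
      mid_att = if (depth %in% attention_levels) attention_init(ch[depth + 1L]),
      mid2 = resblock_init(ch[depth + 1L], ch[depth + 1L], time_dim),
      dec = dec,
      tail = conv_init(3, 3, ch[1L], 1L, zero = TRUE)
    )
  })
  params <- params[!vapply(params, is.null, logical(1))]
  new_noise_predictor(
    "unet", mode, params,
    config = list(base_channels = as.integer(base_channels),
      depth = as.integer(depth), attention_levels = as.integer(attention_levels),
      n_heads = as.integer(n_heads), time_dim = as.integer(time_dim),
      in_channels = cin)
  )
}

unet_forward <- function(p, input, t, train = FALSE) {
  pr <- p$params
  nh <- p$config$n_heads
  depth <- p$config$depth
  temb <- time_embedding(t, p$config$time_dim)
  tm <- time_mlp_fwd(temb, pr$tmlp)
  cache <- list(input = input, tm = tm)

  h <- conv3x3(input, pr$head)
  skips <- vector("list", depth)
  enc_cache <- vector("list", depth)
  for (l in seq_len(depth)) {
    ec <- list()
    rb <- resblock_fwd(h, pr$enc[[l]]$res, tm$h, act = "silu")
    ec$res <- rb$cache
    h <- rb$out
    if (!is.null(pr$enc[[l]]$att)) {
      at <- attention_fwd(h, pr$enc[[l]]$att, nh)
      ec$att <- at$cache
      h <- at$out
    }
    skips[[l]] <- h
    ec$pre_pool_dim <- dim(h)
    pooled <- avgpool2_fwd(h)
    ec$pooled <- pooled
    h <- conv3x3(pooled, pr$enc[[l]]$down)
    enc_cache[[l]] <- ec
  }

  rb <- resblock_fwd(h, pr$mid1, tm$h, act = "silu")
  cache$mid1 <- rb$cache; h <- rb$out
  if (!is.null(pr$mid_att)) {
    at <- attention_fwd(h, pr$mid_att, nh)
    cache$mid_att <- at$cache
    h <- at$out
  }
  rb <- resblock_fwd(h, pr$mid2, tm$h, act = "silu")
  cache$mid2 <- rb$cache; h <- rb$out

  dec_cache <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    dc <- list()
    up <- upsample2_fwd(h)
    dc$up_in <- up
    h <- conv3x3(up, pr$dec[[l]]$up)
    d <- dim(h)
    cat_in <- array(0, c(d[1], d[2], 2L * d[3], d[4]))
    cat_in[, , seq_len(d[3]), ] <- h
    cat_in[, , d[3] + seq_len(d[3]), ] <- skips[[l]]
    dc$nch <- d[3]
    rb <- resblock_fwd(cat_in, pr$dec[[l]]$res, tm$h, act = "silu")
    dc$res <- rb$cache
    h <- rb$out
    if (!is.null(pr$dec[[l]]$att)) {
      at <- attention_fwd(h, pr$dec[[l]]$att, nh)
      dc$att <- at$cache
      h <- at$out
    }
    dec_cache[[l]] <- dc
  }
  cache$enc <- enc_cache
  cache$dec <- dec_cache
  cache$tail_in <- h
  out <- conv3x3(h, pr$tail)
  list(out = out, cache = if (train) cache)
}

unet_backward <- function(p, cache, gout) {
  pr <- p$params
  depth <- p$config$depth
  th <- cache$tm$h
  gh_time <- matrix(0, nrow(th), ncol(th))
  grads <- list()

  gt <- conv3x3_grad(cache$tail_in, pr$tail, gout)
  grads$tail <- list(w = gt$gw, b = gt$gb)
  g <- gt$gx
  g_skips <- vector("list", depth)
  dec_grads <- vector("list", depth)
  for (l in seq_len(depth)) {               # reverse of the decoder loop
    dc <- cache$dec[[l]]
    dg <- list()
    if (!is.null(pr$dec[[l]]$att)) {
      ab <- attention_bwd(dc$att, pr$dec[[l]]$att, g)
      dg$att <- ab$grads
      g <- ab$gx
    }
    bb <- resblock_bwd(dc$res, pr$dec[[l]]$res, th, g)
    gh_time <- gh_time + bb$gh
    nch <- dc$nch
    g_up_out <- bb$gx[, , seq_len(nch), , drop = FALSE]
    g_skips[[l]] <- bb$gx[, , nch + seq_len(nch), , drop = FALSE]
    gu <- conv3x3_grad(dc$up_in, pr$dec[[l]]$up, g_up_out)
    dg$up <- list(w = gu$gw, b = gu$gb)
    dg$res <- bb$grads
    dec_grads[[l]] <- dg[names(pr$dec[[l]])]
    g <- upsample2_bwd(gu$gx)
  }

  bb <- resblock_bwd(cache$mid2, pr$mid2, th, g)
  grads$mid2 <- bb$grads; gh_time <- gh_time + bb$gh; g <- bb$gx
  if (!is.null(pr$mid_att)) {
    ab <- attention_bwd(cache$mid_att, pr$mid_att, g)
    grads$mid_att <- ab$grads
    g <- ab$gx
  }
  bb <- resblock_bwd(cache$mid1, pr$mid1, th, g)
  grads$mid1 <- bb$grads; gh_time <- gh_time + bb$gh; g <- bb$gx

  enc_grads <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    ec <- cache$enc[[l]]
    eg <- list()
    gd <- conv3x3_grad(ec$pooled, pr$enc[[l]]$down, g)
    eg$down <- list(w = gd$gw, b = gd$gb)
    g <- avgpool2_bwd(gd$gx, ec$pre_pool_dim) + g_skips[[l]]
    if (!is.null(pr$enc[[l]]$att)) {
      ab <- attention_bwd(ec$att, pr$enc[[l]]$att, g)
      eg$att <- ab$grads
      g <- ab$gx
    }
    bb <- resblock_bwd(ec$res, pr$enc[[l]]$res, th, g)
    eg$res <- bb$grads
    gh_time <- gh_time + bb$gh
    g <- bb$gx
    enc_grads[[l]] <- eg[names(pr$enc[[l]])]
  }

  gh_head <- conv3x3_grad(cache$input, pr$head, g)
  grads$head <- list(w = gh_head$gw, b = gh_head$gb)
  grads$tmlp <- time_mlp_bwd(cache$tm, pr$tmlp, gh_time)
  grads$enc <- enc_grads
  grads$dec <- dec_grads
  grads[names(pr)]
}
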