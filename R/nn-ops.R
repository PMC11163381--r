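# Layer primitives for the noise-predictor backbones.
#
# All activations use the layout (H, W, C, B): spatial, channel, batch.
# The 3x3 convolution runs in compiled code (src/conv3x3.cpp); everything
# else is plain vectorized R. Each *_fwd returns what its *_bwd needs.

conv_init <- function(kh, kw, cin, cout, zero = FALSE) {
  w <- if (zero) {
    array(0, c(kh, kw, cin, cout))
  } else {
    # He initialization: variance 2 / fan-in keeps ReLU activations scaled
    array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
      c(kh, kw, cin, cout))
  }
  list(w = w, b = numeric(cout))
}

dense_init <- function(din, dout, zero = FALSE) {
  w <- if (zero) matrix(0, din, dout) else
    matrix(rnorm(din * dout, sd = sqrt(1 / din)), din, dout)
  list(w = w, b = numeric(dout))
}

conv3x3 <- function(x, p) conv3x3_fwd(x, p$w, p$b)

conv3x3_grad <- function(x, p, gy) conv3x3_bwd(x, p$w, gy)

conv1x1 <- function(x, p) {
  d <- dim(x); hw <- d[1] * d[2]
  out <- array(0, c(d[1], d[2], ncol(p$w), d[4]))
  for (b in seq_len(d[4])) {
    xm <- matrix(x[, , , b], hw, d[3])
    out[, , , b] <- xm %*% p$w + rep(p$b, each = hw)
  }
  out
}

conv1x1_grad <- function(x, p, gy) {
  d <- dim(x); hw <- d[1] * d[2]; cout <- ncol(p$w)
  gx <- array(0, dim(x))
  gw <- matrix(0, d[3], cout)
  gb <- numeric(cout)
  for (b in seq_len(d[4])) {
    xm <- matrix(x[, , , b], hw, d[3])
    gm <- matrix(gy[, , , b], hw, cout)
    gw <- gw + crossprod(xm, gm)
    gb <- gb + colSums(gm)
    gx[, , , b] <- gm %*% t(p$w)
  }
  list(gx = gx, gw = gw, gb = gb)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, gy) gy * (x > 0)

silu_fwd <- function(x) x * stats::plogis(x)
silu_bwd <- function(x, gy) {
  s <- stats::plogis(x)
  gy * (s * (1 + x * (1 - s)))
}

# 2x2 average pooling (stride 2); H, W must be even.
avgpool2_fwd <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  (x[io, jo, , , drop = FALSE] + x[io + 1L, jo, , , drop = FALSE] +
    x[io, jo + 1L, , , drop = FALSE] + x[io + 1L, jo + 1L, , , drop = FALSE]) / 4
}

avgpool2_bwd <- function(gy, up_dim) {
  gx <- array(0, up_dim)
  io <- seq(1L, up_dim[1], by = 2L); jo <- seq(1L, up_dim[2], by = 2L)
  g <- gy / 4
  gx[io, jo, , ] <- g; gx[io + 1L, jo, , ] <- g
  gx[io, jo + 1L, , ] <- g; gx[io + 1L, jo + 1L, , ] <- g
  gx
}

# Nearest-neighbour x2 upsampling.
upsample2_fwd <- function(x) {
  d <- dim(x)
  ii <- rep(seq_len(d[1]), each = 2L)
  jj <- rep(seq_len(d[2]), each = 2L)
  x[ii, jj, , , drop = FALSE]
}

upsample2_bwd <- function(gy) {
  d <- dim(gy)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  gy[io, jo, , , drop = FALSE] + gy[io + 1L, jo, , , drop = FALSE] +
    gy[io, jo + 1L, , , drop = FALSE] + gy[io + 1L, jo + 1L, , , drop = FALSE]
}

# Sinusoidal embedding of integer time steps; distinct t map to distinct
# vectors as long as t stays below the largest wavelength (10^4 here).
time_embedding <- function(t, dim) {
  half <- dim %/% 2L
  freq <- exp(-log(10000) * (seq_len(half) - 1) / half)
  ang <- outer(freq, as.numeric(t))          # half x B
  rbind(sin(ang), cos(ang))                  # dim x B
}

# Shared time MLP trunk: h = silu(W1' e + b1), consumed by per-block
# projections that turn h into per-channel biases.
time_mlp_fwd <- function(temb, p) {
  pre <- crossprod(p$w1$w, temb) + p$w1$b    # dim x B
  list(h = silu_fwd(pre), pre = pre, temb = temb)
}

time_mlp_bwd <- function(cache, p, gh) {
  gpre <- silu_bwd(cache$pre, gh)
  list(
    w1 = list(w = cache$temb %*% t(gpre), b = rowSums(gpre))
  )
}

tproj_fwd <- function(h, p) crossprod(p$w, h) + p$b   # channels x B

tproj_bwd <- function(h, p, gtb) {
  list(gw = h %*% t(gtb), gb = rowSums(gtb), gh = p$w %*% gtb)
}

# Add a per-(channel, sample) bias to an (H, W, C, B) activation.
add_channel_bias <- function(x, tb) {
  d <- dim(x)
  x + array(rep(tb, each = d[1] * d[2]), d)
}

channel_bias_grad <- function(gy) {
  d <- dim(gy)
  # sum over the spatial plane for every (channel, sample)
  matrix(colSums(matrix(gy, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

# ---- multi-head self-attention over the H*W token grid -----------------

attention_init <- function(channels) {
  # zero-initialized output projection: the attention layer starts as identity
  list(
    wq = dense_init(channels, channels), wk = dense_init(channels, channels),
    wv = dense_init(channels, channels),
    wo = dense_init(channels, channels, zero = TRUE)
  )
}

attention_fwd <- function(x, p, n_heads) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  dh <- C %/% n_heads
  out <- array(0, d)
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    X <- matrix(x[, , , b], hw, C)
    Q <- X %*% p$wq$w + rep(p$wq$b, each = hw)
    K <- X %*% p$wk$w + rep(p$wk$b, each = hw)
    V <- X %*% p$wv$w + rep(p$wv$b, each = hw)
    O <- matrix(0, hw, C)
    A_list <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
      S <- S - apply(S, 1L, max)             # row-stabilized softmax
      A <- exp(S); A <- A / rowSums(A)
      A_list[[h]] <- A
      O[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    Y <- O %*% p$wo$w + rep(p$wo$b, each = hw)
    out[, , , b] <- x[, , , b] + array(Y, c(d[1], d[2], C))
    caches[[b]] <- list(X = X, Q = Q, K = K, V = V, O = O, A = A_list)
  }
  list(out = out, cache = list(per_b = caches, dim = d, n_heads = n_heads))
}

attention_bwd <- function(cache, p, gy) {
  d <- cache$dim; hw <- d[1] * d[2]; C <- d[3]; B <- d[4]
  nh <- cache$n_heads; dh <- C %/% nh
  gx <- array(0, d)
  g <- list(
    wq = list(w = matrix(0, C, C), b = numeric(C)),
    wk = list(w = matrix(0, C, C), b = numeric(C)),
    wv = list(w = matrix(0, C, C), b = numeric(C)),
    wo = list(w = matrix(0, C, C), b = numeric(C))
  )
  for (b in seq_len(B)) {
    cb <- cache$per_b[[b]]
    gY <- matrix(gy[, , , b], hw, C)
    g$wo$w <- g$wo$w + crossprod(cb$O, gY)
    g$wo$b <- g$wo$b + colSums(gY)
    gO <- gY %*% t(p$wo$w)
    gQ <- matrix(0, hw, C); gK <- matrix(0, hw, C); gV <- matrix(0, hw, C)
    for (h in seq_len(nh)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cb$A[[h]]
      gOh <- gO[, idx, drop = FALSE]
      gA <- tcrossprod(gOh, cb$V[, idx, drop = FALSE])
      gV[, idx] <- crossprod(A, gOh)
      # softmax backward, rowwise: gS = A * (gA - rowSums(gA * A))
      gS <- A * (gA - rowSums(gA * A))
      gS <- gS / sqrt(dh)
      gQ[, idx] <- gS %*% cb$K[, idx, drop = FALSE]
      gK[, idx] <- crossprod(gS, cb$Q[, idx, drop = FALSE])
    }
    g$wq$w <- g$wq$w + crossprod(cb$X, gQ); g$wq$b <- g$wq$b + colSums(gQ)
    g$wk$w <- g$wk$w + crossprod(cb$X, gK); g$wk$b <- g$wk$b + colSums(gK)
    g$wv$w <- g$wv$w + crossprod(cb$X, gV); g$wv$b <- g$wv$b + colSums(gV)
    gX <- gQ %*% t(p$wq$w) + gK %*% t(p$wk$w) + gV %*% t(p$wv$w) + gY
    gx[, , , b] <- array(gX, c(d[1], d[2], C))
  }
  list(gx = gx, grads = g)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = param_map(params, function(x) x * 0),
    v = param_map(params, function(x) x * 0),
    step = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$step
  c2 <- 1 - beta2^state$step
  upd <- param_map2(state$m, state$v, function(m, v) {
    (m / c1) / (sqrt(v / c2) + eps)
  })
  params <- param_map2(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}
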