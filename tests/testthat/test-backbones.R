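test_that("predictors keep the spatial shape and produce finite output", {
  y <- matrix(rnorm(64 * 64), 64)
  for (build in list(tiny_residual, tiny_unet)) {
    p <- build(seed = 1)
    out <- predict_noise(p, y, t = 10)
    expect_equal(dim(out), dim(y))
    expect_true(all(is.finite(out)))
    # batch form
    yb <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
    outb <- predict_noise(p, yb, t = c(1, 25, 50))
    expect_equal(dim(outb), dim(yb))
  }
})

test_that("conditional builds take exactly twice the input channels", {
  pr_u <- tiny_residual("unconditional")
  pr_c <- tiny_residual("conditional")
  expect_equal(dim(pr_u$params$head$w)[3], 1L)
  expect_equal(dim(pr_c$params$head$w)[3], 2L)
  expect_equal(pr_c$config$in_channels, 2L * pr_u$config$in_channels)

  pu_u <- tiny_unet("unconditional")
  pu_c <- tiny_unet("conditional")
  expect_equal(dim(pu_c$params$head$w)[3], 2L * dim(pu_u$params$head$w)[3])

  # the parameter surplus is exactly the extra first-layer weights
  expect_equal(count_parameters(pr_c) - count_parameters(pr_u),
    prod(dim(pr_u$params$head$w)))
  expect_error(predict_noise(pr_c, matrix(0, 8, 8), 1),
    class = "hicdiffuse_config_error")
})

test_that("parameter counting matches closed forms for convolutions", {
  # a single 3x3 conv, 1 -> 1 channel, with bias
  single <- hicdiffuse:::conv_init(3, 3, 1, 1)
  expect_equal(length(single$w) + length(single$b), 10L)
  # doubling channels about quadruples 3x3 conv parameters
  c1 <- hicdiffuse:::conv_init(3, 3, 8, 8)
  c2 <- hicdiffuse:::conv_init(3, 3, 16, 16)
  expect_equal(length(c2$w), 4L * length(c1$w))

  p <- tiny_residual()
  ch <- p$config$channels; nb <- p$config$n_blocks; td <- p$config$time_dim
  manual <- (9 * ch + ch) +                       # head
    nb * (9 * ch^2 + ch + 9 * ch^2 + ch + td * ch + ch) +  # blocks
    (td^2 + td) +                                 # time MLP
    (9 * ch + 1)                                  # tail
  expect_equal(count_parameters(p), manual)
})

test_that("a zero-initialized tail makes the untrained network output zero", {
  for (build in list(tiny_residual, tiny_unet)) {
    p <- build(seed = 3)
    out <- predict_noise(p, matrix(rnorm(64 * 64), 64), t = 5)
    expect_equal(max(abs(out)), 0)
  }
})

test_that("builds and forward passes are deterministic under a fixed seed", {
  p1 <- tiny_residual(seed = 9)
  p2 <- tiny_residual(seed = 9)
  expect_identical(p1$params, p2$params)
  y <- matrix(rnorm(32 * 32), 32)
  expect_identical(predict_noise(p1, y, 3), predict_noise(p2, y, 3))
})

test_that("time embeddings separate distinct steps", {
  emb <- hicdiffuse:::time_embedding(1:1000, 64)
  expect_equal(ncol(unique(t(emb))), 64L)
  expect_equal(nrow(unique(t(emb))), 1000L)
})

test_that("the U-Net halves resolution per level and checks divisibility", {
  p <- tiny_unet(seed = 2)
  input <- hicdiffuse:::predictor_input(p, array(rnorm(64 * 64), c(64, 64, 1)))
  fw <- hicdiffuse:::unet_forward(p, input, t = 4, train = TRUE)
  # bottleneck cache spatial size is 64 / 2^depth = 16
  expect_equal(dim(fw$cache$mid1$x)[1:2], c(16L, 16L))
  expect_error(build_unet_predictor(8, depth = 2, tile_size = 50),
    class = "hicdiffuse_range_error")
  expect_error(build_unet_predictor(8, depth = 2, n_heads = 3),
    class = "hicdiffuse_range_error")
})

test_that("gradients flow to essentially every parameter", {
  set.seed(21)
  for (build in list(tiny_residual, tiny_unet)) {
    for (mode in c("unconditional", "conditional")) {
      p <- build(mode = mode, seed = 4)
      # the tail (and attention output) convs start at zero by design, which
      # gates all upstream gradients; give every zero-initialized layer
      # generic weights so the flow through the whole graph is visible
      p$params <- hicdiffuse:::param_map(p$params, function(a) {
        if (is.null(dim(a)) || any(a != 0)) return(a)
        array(rnorm(length(a), sd = 0.05), dim(a))
      })
      y0 <- array(runif(64 * 64 * 2, -1, 1), c(64, 64, 2))
      x <- if (mode == "conditional") y0 + rnorm(length(y0), sd = 0.1)
      sched <- make_schedule("linear", T = 20)
      obj <- hicdiffuse:::batch_objective(p, y0, sched, x = x,
        with_grads = TRUE)
      leaves <- hicdiffuse:::param_flatten(obj$grads)
      all_g <- unlist(leaves)
      expect_true(all(is.finite(all_g)))
      expect_gte(mean(all_g != 0), 0.99)
    }
  }
})

test_that("analytic gradients agree with directional finite differences", {
  set.seed(31)
  for (build in list(tiny_residual, tiny_unet)) {
    p <- build(mode = "conditional", seed = 13)
    n <- 16L; B <- 2L
    y <- array(rnorm(n * n * B), c(n, n, B))
    x <- array(rnorm(n * n * B), c(n, n, B))
    tvec <- c(3, 11)
    eps <- array(rnorm(n * n * B), c(n, n, B))
    loss_of <- function(pp) {
      input <- hicdiffuse:::predictor_input(pp, y, x)
      out <- hicdiffuse:::predictor_forward(pp, input, tvec)$out
      mean((array(out, dim(y)) - eps)^2)
    }
    input <- hicdiffuse:::predictor_input(p, y, x)
    fw <- hicdiffuse:::predictor_forward(p, input, tvec, train = TRUE)
    gout <- array(2 * (array(fw$out, dim(y)) - eps) / length(y), dim(fw$out))
    grads <- hicdiffuse:::predictor_backward(p, fw$cache, gout)
    u <- hicdiffuse:::param_map(p$params, function(a) {
      r <- rnorm(length(a))
      if (!is.null(dim(a))) dim(r) <- dim(a)
      r
    })
    unorm <- sqrt(hicdiffuse:::param_sum(u, function(a) sum(a^2)))
    u <- hicdiffuse:::param_map(u, function(a) a / unorm)
    h <- 1e-3
    pp <- p
    pp$params <- hicdiffuse:::param_map2(p$params, u, function(a, d) a + h * d)
    pm <- p
    pm$params <- hicdiffuse:::param_map2(p$params, u, function(a, d) a - h * d)
    num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
    ana <- hicdiffuse:::param_sum(
      hicdiffuse:::param_map2(grads, u, function(g, d) sum(g * d)), sum)
    expect_equal(ana, num, tolerance = 1e-3)
  }
})
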