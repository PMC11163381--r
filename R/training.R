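# Training: minimize ||eps - f_theta(y_t, t[, x])||^2 over random (t, eps).

as_tile_array <- function(tiles) {
  if (is.array(tiles) && length(dim(tiles)) == 3L) return(unclass(tiles))
  if (is.matrix(tiles)) return(array(tiles, c(dim(tiles), 1L)))
  if (is.list(tiles) && length(tiles) > 0L) {
    d <- dim(tiles[[1L]])
    arr <- array(0, c(d, length(tiles)))
    for (i in seq_along(tiles)) arr[, , i] <- unclass(tiles[[i]])
    return(arr)
  }
  abort("empty batch.", class = "hicdiffuse_range_error")
}

# Draw (t, eps), push the batch through the forward process and the
# predictor, and return the loss (plus gradients when requested).
batch_objective <- function(predictor, y0, sched, x = NULL, with_grads = FALSE) {
  d <- dim(y0)
  B <- d[3]
  t <- sample.int(sched$T, B, replace = TRUE)
  eps <- array(rnorm(length(y0)), d)
  ab <- sched$alpha_bar[t]
  scale_s <- rep(sqrt(ab), each = d[1] * d[2])
  scale_n <- rep(sqrt(1 - ab), each = d[1] * d[2])
  yt <- y0 * scale_s + eps * scale_n
  input <- predictor_input(predictor, yt, x)
  fw <- predictor_forward(predictor, input, t, train = with_grads)
  resid <- array(fw$out, d) - eps
  loss <- mean(resid^2)
  if (!with_grads) return(list(loss = loss))
  gout <- array(2 * resid / length(resid), dim(fw$out))
  list(loss = loss, grads = predictor_backward(predictor, fw$cache, gout))
}

#' Unsupervised (unconditional) training loss
#'
#' For each clean tile a step `t ~ Uniform{1..T}` and a noise field
#' `eps ~ N(0, I)` are drawn, the forward process produces `y_t`, and the
#' loss is the mean squared error between `eps` and the predictor's estimate
#' `f(y_t, t)`, averaged over the batch. A perfect (oracle) predictor gives
#' exactly 0; a predictor that always outputs 0 has expectation 1 per entry.
#'
#' @param predictor Noise predictor (or plain function `f(y, t, x)`).
#' @param y0_batch Clean tiles: list of matrices, a matrix, or an
#'   `(n, n, B)` array, in model range.
#' @param sched A [make_schedule()] object.
#' @param seed Optional seed making the drawn `(t, eps)` reproducible.
#' @return Scalar loss.
#' @export
loss_unsupervised <- function(predictor, y0_batch, sched, seed = NULL) {
  y0 <- as_tile_array(y0_batch)
  with_seed(seed, {
    if (is.function(predictor)) {
      fn_loss(predictor, y0, sched, x = NULL)
    } else {
      batch_objective(predictor, y0, sched)$loss
    }
  })
}

#' Supervised (conditional) training loss
#'
#' Identical to [loss_unsupervised()] except that the predictor also receives
#' the fixed corrupted observation `x` of each tile (channel-concatenated),
#' the conditioning of the supervised mode.
#'
#' @inheritParams loss_unsupervised
#' @param pairs A tibble/list with elements `clean` and `noisy` (aligned
#'   list-columns of tiles, e.g. from [crop_training_pairs()]), or a list of
#'   `list(clean =, noisy =)` pairs.
#' @export
loss_supervised <- function(predictor, pairs, sched, seed = NULL) {
  if (is.null(pairs[["clean"]]) || is.null(pairs[["noisy"]])) {
    abort("supervised loss needs paired `clean` and `noisy` tiles.",
      class = "hicdiffuse_config_error")
  }
  y0 <- as_tile_array(pairs[["clean"]])
  x <- as_tile_array(pairs[["noisy"]])
  assert_same_shape(y0, x, "clean and noisy batches")
  with_seed(seed, {
    if (is.function(predictor)) {
      fn_loss(predictor, y0, sched, x = x)
    } else {
      batch_objective(predictor, y0, sched, x = x)$loss
    }
  })
}

# Loss path for plain-function predictors (oracles in tests).
fn_loss <- function(predictor, y0, sched, x = NULL) {
  d <- dim(y0)
  t <- sample.int(sched$T, d[3], replace = TRUE)
  eps <- array(rnorm(length(y0)), d)
  ab <- sched$alpha_bar[t]
  yt <- y0 * rep(sqrt(ab), each = d[1] * d[2]) +
    eps * rep(sqrt(1 - ab), each = d[1] * d[2])
  tot <- 0
  for (b in seq_len(d[3])) {
    eh <- predictor(yt[, , b], t[b], if (!is.null(x)) x[, , b])
    tot <- tot + mean((unclass(eh) - eps[, , b])^2)
  }
  tot / d[3]
}

#' Training configuration
#'
#' @param mode `"unsupervised"` (clean tiles only) or `"supervised"`
#'   (paired clean/noisy tiles).
#' @param epochs Number of passes over the training tiles.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size. `1e-3` suits the scaled-down runs;
#'   large full-scale models typically use `1e-4`.
#' @param seed Seed controlling shuffling, `(t, eps)` draws and
#'   initialization-independent reproducibility of the whole fit.
#' @param validation `"loss"` (denoising objective on held-out tiles, cheap)
#'   or `"psnr"` (deterministic reverse-chain denoising of the held-out noisy
#'   tiles scored against their clean references; needs `noisy` tiles and
#'   `sigma_x`).
#' @param val_fraction Fraction of tiles held out for validation.
#' @param sigma_x Observation noise level used by the `"psnr"` criterion.
#' @param verbose Print one line per epoch?
#' @export
train_config <- function(mode = c("unsupervised", "supervised"), epochs = 30L,
                         batch_size = 8L, learning_rate = 1e-3, seed = 1L,
                         validation = c("loss", "psnr"), val_fraction = 0.15,
                         sigma_x = 0.1, verbose = FALSE) {
  structure(
    list(
      mode = match.arg(mode), epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      seed = as.integer(seed), validation = match.arg(validation),
      val_fraction = val_fraction, sigma_x = sigma_x, verbose = isTRUE(verbose)
    ),
    class = "train_config"
  )
}

#' Fit a noise predictor
#'
#' Runs `epochs` of minibatch Adam on the denoising objective, evaluates the
#' validation criterion after every epoch on a held-out split (with a fixed
#' evaluation seed, so epochs are comparable), and returns the checkpoint
#' that minimizes it. The whole run is bit-reproducible given
#' `config$seed`.
#'
#' @param predictor A built noise predictor; its mode must agree with
#'   `config$mode` (`supervised` needs a conditional predictor).
#' @param data Tiles: a tibble with list-column `clean` (plus `noisy` for
#'   supervised training, which also conditions on it), or a plain list of
#'   clean tile matrices.
#' @param sched A [make_schedule()] object.
#' @param config A [train_config()].
#' @return A `hicdiff_fit`: the best predictor, a per-epoch `history`
#'   tibble, the config and the schedule.
#' @export
fit_predictor <- function(predictor, data, sched, config = train_config()) {
  if (is.list(data) && is.null(data[["clean"]])) data <- tibble::tibble(clean = data)
  supervised <- config$mode == "supervised"
  if (supervised && is.null(data[["noisy"]])) {
    abort("supervised training needs paired noisy tiles (`data$noisy`).",
      class = "hicdiffuse_config_error")
  }
  if (supervised && predictor$mode != "conditional") {
    abort("supervised training needs a conditional predictor.",
      class = "hicdiffuse_config_error")
  }
  if (!supervised && predictor$mode == "conditional") {
    abort("unsupervised training needs an unconditional predictor.",
      class = "hicdiffuse_config_error")
  }
  n <- length(data$clean)
  if (n < 2L) abort("need at least 2 tiles.", class = "hicdiffuse_range_error")

  with_seed(config$seed, {
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)
    y0_all <- as_tile_array(data$clean)
    x_all <- if (supervised) as_tile_array(data[["noisy"]])
    eval_seed <- derive_seed(config$seed, 999L)

    eval_criterion <- function() {
      if (config$validation == "loss") {
        yv <- y0_all[, , val_idx, drop = FALSE]
        xv <- if (supervised) x_all[, , val_idx, drop = FALSE]
        with_seed(eval_seed,
          batch_objective(predictor, yv, sched, x = xv)$loss)
      } else {
        if (is.null(data[["noisy"]])) {
          abort("psnr validation needs noisy tiles.",
            class = "hicdiffuse_config_error")
        }
        xv <- as_tile_array(data[["noisy"]])[, , val_idx, drop = FALSE]
        t0 <- match_start_time(config$sigma_x, sched)
        y_init <- sqrt(sched$alpha_bar[t0]) * xv
        yhat <- reverse_denoise(predictor, sched,
          x = if (supervised) xv, start_t = t0, y_start = y_init,
          stochastic = FALSE)
        vals <- vapply(seq_along(val_idx), function(k) {
          psnr_map(from_model_range(y0_all[, , val_idx[k]]),
            from_model_range(yhat[, , k]))
        }, numeric(1))
        -mean(vals)   # minimized criterion
      }
    }

    state <- adam_init(predictor$params)
    best <- list(criterion = Inf, params = predictor$params, epoch = 0L)
    history <- vector("list", config$epochs)
    t_start <- proc.time()[["elapsed"]]
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (bidx in batches) {
        yb <- y0_all[, , bidx, drop = FALSE]
        xb <- if (supervised) x_all[, , bidx, drop = FALSE]
        obj <- batch_objective(predictor, yb, sched, x = xb, with_grads = TRUE)
        if (!is.finite(obj$loss)) {
          abort(sprintf(
            "training diverged at epoch %d (loss = %g); lower the learning rate.",
            epoch, obj$loss), class = "hicdiffuse_divergence_error")
        }
        upd <- adam_step(predictor$params, obj$grads, state,
          lr = config$learning_rate)
        predictor$params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + obj$loss * length(bidx)
      }
      epoch_loss <- epoch_loss / length(ord)
      crit <- eval_criterion()
      is_best <- crit < best$criterion
      if (is_best) best <- list(criterion = crit, params = predictor$params,
        epoch = epoch)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = epoch_loss, val_criterion = crit,
        best = is_best, elapsed = proc.time()[["elapsed"]] - t_start
      )
      if (config$verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f%s",
          epoch, epoch_loss, crit, if (is_best) "  *" else ""))
      }
    }
    predictor$params <- best$params
    structure(
      list(predictor = predictor, history = dplyr::bind_rows(history),
        config = config, schedule = sched, best_epoch = best$epoch,
        best_criterion = best$criterion),
      class = "hicdiff_fit"
    )
  })
}

#' @export
print.hicdiff_fit <- function(x, ...) {
  cat(sprintf(
    "<hicdiff_fit> %s %s: %d epochs, best epoch %d (criterion %.5g)\n",
    x$config$mode, x$predictor$backbone, nrow(x$history), x$best_epoch,
    x$best_criterion
  ))
  invisible(x)
}

#' @export
tidy.hicdiff_fit <- function(x, ...) x$history

#' @export
glance.hicdiff_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode,
    backbone = x$predictor$backbone,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_criterion = x$best_criterion,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    parameters = count_parameters(x$predictor)
  )
}

#' @export
autoplot.hicdiff_fit <- function(object, ...) {
  h <- object$history
  df <- tibble::tibble(
    epoch = rep(h$epoch, 2),
    value = c(h$train_loss, h$val_criterion),
    series = rep(c("train loss", "validation criterion"), each = nrow(h))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
      colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a training checkpoint
#'
#' The checkpoint is a single RDS archive holding the predictor (weights +
#' architecture config), the training history and configuration, so a reload
#' fully reproduces the inference-time model.
#'
#' @param fit A `hicdiff_fit` or a bare `noise_predictor`.
#' @param path Destination file.
#' @return `path` invisibly; `load_checkpoint()` returns the stored object.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(format = "hicdiffuse-checkpoint", version = 1L, object = fit),
    path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "hicdiffuse-checkpoint")) {
    abort(sprintf("%s is not a hicdiffuse checkpoint.", path),
      class = "hicdiffuse_io_error")
  }
  ck$object
}
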