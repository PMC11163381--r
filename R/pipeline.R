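#' Denoise a full contact matrix by tiled reverse diffusion
#'
#' The matrix is cut into `tile_size x tile_size` tiles (zero-padded at the
#' edges), every tile is pushed through the reverse chain, and the tiles are
#' reassembled with the padding removed. Raw count maps are first normalized
#' to `[0, 1]` and rescaled to the `[-1, 1]` model range; model-range inputs
#' are used as-is.
#'
#' With `start_from = "observation"` (default) the chain starts at the step
#' whose noise-to-signal ratio matches `sigma_x` ([match_start_time()]),
#' from the correspondingly scaled observation — this grounds both the
#' unconditional and the conditional chain in the data. With
#' `start_from = "noise"` the full chain runs from `y_T ~ N(0, I)`
#' (conditional predictors only: an unconditional chain from pure noise
#' generates a map rather than denoising one).
#'
#' @param input A [contact_map()] (raw counts) or a model-range matrix.
#' @param predictor Trained noise predictor (or a `hicdiff_fit`).
#' @param sched Schedule; defaults to the one stored in a `hicdiff_fit`.
#' @param sigma_x Noise level of the observation.
#' @param tile_size Tile side length.
#' @param start_from `"observation"` or `"noise"`.
#' @param stochastic Sample the reverse chain (TRUE) or take the mean path?
#' @param seed Seed for the chain (and `y_T` draw).
#' @param variance Reverse-variance variant, see [posterior_mean()].
#' @param clip_quantile Normalization quantile for raw-count input.
#' @param chunk_size Tiles denoised per batch (memory/speed trade-off).
#' @return The denoised map on the `[0, 1]` scale (a `unit_map` matrix of
#'   the input's original size).
#' @export
denoise_map <- function(input, predictor, sched = NULL, sigma_x = 0.1,
                        tile_size = 64L,
                        start_from = c("observation", "noise"),
                        stochastic = FALSE, seed = NULL,
                        variance = c("sqrt_one_minus_abar", "beta_tilde"),
                        clip_quantile = 0.999, chunk_size = 32L) {
  start_from <- match.arg(start_from)
  variance <- match.arg(variance)
  if (inherits(predictor, "hicdiff_fit")) {
    sched <- sched %||% predictor$schedule
    predictor <- predictor$predictor
  }
  if (is.null(sched)) abort("`sched` is required for a bare predictor.",
    class = "hicdiffuse_config_error")
  x_model <- if (inherits(input, "contact_map")) {
    to_model_range(normalize_unit(input, clip_quantile = clip_quantile))
  } else {
    unclass(input)
  }
  conditional <- !is.function(predictor) && predictor$mode == "conditional"
  if (start_from == "noise" && !conditional) {
    abort("start_from = 'noise' needs a conditional predictor for denoising.",
      class = "hicdiffuse_config_error")
  }
  tl <- tile_map(x_model, tile_size)
  xarr <- as_tile_array(tl$tiles)
  nb <- dim(xarr)[3]
  t0 <- if (start_from == "observation") match_start_time(sigma_x, sched)
    else sched$T
  out <- array(0, dim(xarr))
  chunks <- split(seq_len(nb), ceiling(seq_len(nb) / chunk_size))
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    xc <- xarr[, , idx, drop = FALSE]
    y_init <- if (start_from == "observation") {
      sqrt(sched$alpha_bar[t0]) * xc
    } else NULL
    out[, , idx] <- reverse_denoise(
      predictor, sched,
      x = if (conditional) xc,
      start_t = t0, y_start = y_init, stochastic = stochastic,
      seed = if (!is.null(seed)) derive_seed(seed, ci),
      variance = variance
    )
  }
  full <- assemble_tiles(
    lapply(seq_len(nb), function(b) out[, , b]), tl$plan
  )
  from_model_range(full, clip = TRUE)
}

#' Scaled-down denoising benchmark
#'
#' The package's end-to-end experiment at desk scale: generate synthetic
#' single-cell-like 64x64 tiles, corrupt them at `sigma_x`, train the tiny
#' residual backbone in both the unsupervised and the supervised mode, run
#' tiled reverse-chain denoising on held-out tiles, and score noisy input
#' and both denoised outputs against the clean references with the full
#' metric suite.
#'
#' Defaults follow the scaled study conditions: 200 training tiles, noise
#' level 0.1, a 4-block/32-channel residual predictor, T = 50 diffusion
#' steps, 30 epochs; 30 validation and 40 test tiles are generated on top
#' of the training set.
#'
#' @param n_train,n_val,n_test Tile counts per split.
#' @param sigma_x Observation noise level.
#' @param channels,n_blocks Residual backbone size.
#' @param T_steps,schedule_kind Diffusion schedule settings.
#' @param epochs,batch_size,learning_rate Training settings.
#' @param seed Master seed for data, initialization and training.
#' @param modes Which training modes to run.
#' @param params Synthetic generator template for the 64-bin tiles.
#' @param verbose Print per-epoch training lines?
#' @return A list with `metrics` (tibble: one row per condition x metric
#'   summary), `per_tile` (tibble of per-tile scores), and the two fits.
#' @export
run_denoising_benchmark <- function(n_train = 200L, n_val = 30L, n_test = 40L,
                                    sigma_x = 0.1, channels = 32L,
                                    n_blocks = 4L, T_steps = 50L,
                                    schedule_kind = "linear", epochs = 30L,
                                    batch_size = 4L, learning_rate = 2e-3,
                                    seed = 1L,
                                    modes = c("unsupervised", "supervised"),
                                    params = NULL, verbose = FALSE) {
  params <- params %||% synthetic_params(
    n_bins = 64L, decay_exponent = 1, tad_boundaries = c(21L, 42L),
    tad_enrichment = 4, read_depth = 8000, mode = "single_cell",
    keep_fraction = 0.05
  )
  n_all <- n_train + n_val + n_test
  bench <- make_benchmark_set(n_all, params, sigma_levels = sigma_x,
    seed = seed)
  idx_train <- seq_len(n_train)
  idx_val <- n_train + seq_len(n_val)
  idx_test <- n_train + n_val + seq_len(n_test)
  sched <- make_schedule(schedule_kind, T = T_steps)

  train_val <- bench[c(idx_train, idx_val), ]
  data <- tibble::tibble(clean = train_val$clean_model,
    noisy = train_val$noisy)
  val_frac <- n_val / (n_train + n_val)

  fits <- list()
  per_tile <- list()
  for (mode in modes) {
    pred <- if (mode == "supervised") {
      build_residual_predictor(channels, n_blocks, mode = "conditional",
        seed = derive_seed(seed, 11L))
    } else {
      build_residual_predictor(channels, n_blocks, mode = "unconditional",
        seed = derive_seed(seed, 12L))
    }
    cfg <- train_config(mode = mode, epochs = epochs,
      batch_size = batch_size, learning_rate = learning_rate,
      seed = derive_seed(seed, 13L), val_fraction = val_frac,
      sigma_x = sigma_x, verbose = verbose)
    fits[[mode]] <- fit_predictor(pred, data, sched, cfg)
    for (k in idx_test) {
      den <- denoise_map(bench$noisy[[k]], fits[[mode]],
        sigma_x = sigma_x, seed = derive_seed(seed, 100L + k))
      per_tile[[length(per_tile) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(condition = mode, map_id = bench$map_id[k]),
        evaluate_maps(from_model_range(bench$clean_model[[k]]), den,
          space = "unit", max_dist_bins = 32L)
      )
    }
  }
  for (k in idx_test) {
    per_tile[[length(per_tile) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(condition = "noisy_input", map_id = bench$map_id[k]),
      evaluate_maps(bench$clean_model[[k]], bench$noisy[[k]],
        space = "model", max_dist_bins = 32L)
    )
  }
  per_tile <- dplyr::bind_rows(per_tile)
  metrics <- per_tile |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(
      c("psnr", "ssim", "mse", "snr", "hicrep", "insulation_l2"),
      mean), .groups = "drop")
  list(metrics = metrics, per_tile = per_tile, fits = fits,
    n_test = length(idx_test))
}
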