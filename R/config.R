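#' Default run configuration
#'
#' Nested list of every tunable the pipeline understands, with the package
#' defaults. Serialized alongside command outputs for provenance.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    noise = list(sigma = 0.1, symmetric = FALSE, seed = 1L),
    tiling = list(size = 64L, stride = 64L, drop_empty = TRUE),
    diffusion = list(T = 50L, schedule = "linear", beta_start = 1e-4,
      beta_end = 0.02, variance = "sqrt_one_minus_abar"),
    inference = list(stochastic = FALSE, seed = 1L,
      start_from = "observation"),
    model = list(backbone = "residual", channels = 32L, blocks = 4L,
      mode = "unsupervised", time_dim = 64L),
    train = list(epochs = 30L, batch_size = 8L, learning_rate = 1e-3,
      seed = 1L, validation = "loss", val_fraction = 0.15),
    simulate = list(n_bins = 256L, n_maps = 1L, decay_exponent = 1,
      tad_enrichment = 4, read_depth = 1e5, mode = "single_cell",
      keep_fraction = 0.05),
    normalize = list(clip_quantile = 0.999)
  )
}

# Deep-merge b into a (b wins on leaves).
merge_config <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) {
      merge_config(a[[nm]], b[[nm]])
    } else {
      b[[nm]]
    }
  }
  a
}

#' Load a run configuration
#'
#' Merges, in order of increasing precedence: the package defaults, an
#' optional YAML file, and dotted-key command-line overrides such as
#' `"diffusion.T=100"` or `"noise.sigma=0.5"` (values are parsed as YAML, so
#' numbers and booleans come out typed).
#'
#' @param path Optional YAML config file.
#' @param overrides Character vector of `section.key=value` strings.
#' @return The resolved nested configuration list.
#' @export
load_config <- function(path = NULL, overrides = character()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file not found: %s", path),
        class = "hicdiffuse_io_error")
    }
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort(sprintf("override '%s' is not of the form key=value.", ov),
        class = "hicdiffuse_config_error")
    }
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    value <- yaml::yaml.load(kv[2])
    patch <- value
    for (k in rev(keys)) patch <- setNames(list(patch), k)
    cfg <- merge_config(cfg, patch)
  }
  cfg
}

#' Write a resolved configuration next to an output
#'
#' @param cfg Configuration list.
#' @param path Destination YAML file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
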