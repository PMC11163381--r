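#' Parameters of the synthetic Hi-C generator
#'
#' The generator emulates the statistical structure the denoising method
#' assumes: a power-law contact-probability decay with genomic distance
#' (`(1 + d)^-decay_exponent`), multiplicative enrichment inside planted TAD
#' blocks, Poisson-sampled symmetric counts at a given sequencing depth, and
#' — in `single_cell` mode — binomial thinning of the counts to the heavy
#' sparsity characteristic of one-cell assays.
#'
#' @param n_bins Matrix side length.
#' @param decay_exponent Power-law exponent of the distance decay (> 0);
#'   1 is the classic Hi-C value.
#' @param tad_boundaries Strictly increasing interior boundary bin indices
#'   in `(0, n_bins)`; consecutive boundaries delimit TAD blocks. `NULL`
#'   plants a boundary every 32 bins.
#' @param tad_enrichment Multiplicative intensity factor (>= 1) for bin
#'   pairs inside the same TAD.
#' @param read_depth Expected total read pairs on the upper triangle before
#'   thinning. The default (1e5) gives a moderately covered bulk map at a
#'   few hundred bins, and ~90% empty entries after single-cell thinning at
#'   the default keep fraction.
#' @param seed Integer seed; generation is bit-reproducible given it.
#' @param mode `"bulk"` or `"single_cell"`.
#' @param keep_fraction Binomial thinning probability used in single-cell
#'   mode, in (0, 1]. 0.05 mimics the sparsity gap between one cell and a
#'   population.
#' @export
synthetic_params <- function(n_bins = 256L, decay_exponent = 1,
                             tad_boundaries = NULL, tad_enrichment = 4,
                             read_depth = 1e5, seed = 1L,
                             mode = c("bulk", "single_cell"),
                             keep_fraction = 0.05) {
  mode <- match.arg(mode)
  if (is.null(tad_boundaries)) {
    tad_boundaries <- if (n_bins > 32L) seq(32L, n_bins - 1L, by = 32L)
      else integer(0)
  }
  tad_boundaries <- as.integer(tad_boundaries)
  if (length(tad_boundaries)) {
    if (is.unsorted(tad_boundaries, strictly = TRUE) ||
        any(tad_boundaries <= 0L) || any(tad_boundaries >= n_bins)) {
      abort("`tad_boundaries` must be strictly increasing inside (0, n_bins).",
        class = "hicdiffuse_range_error")
    }
  }
  if (decay_exponent <= 0) abort("`decay_exponent` must be > 0.",
    class = "hicdiffuse_range_error")
  if (tad_enrichment < 1) abort("`tad_enrichment` must be >= 1.",
    class = "hicdiffuse_range_error")
  if (keep_fraction <= 0 || keep_fraction > 1) {
    abort("`keep_fraction` must be in (0, 1].", class = "hicdiffuse_range_error")
  }
  structure(
    list(n_bins = as.integer(n_bins), decay_exponent = decay_exponent,
      tad_boundaries = tad_boundaries, tad_enrichment = tad_enrichment,
      read_depth = read_depth, seed = as.integer(seed), mode = mode,
      keep_fraction = keep_fraction),
    class = "synthetic_params"
  )
}

# TAD interval id per bin (1-based); boundaries delimit [0, b1), [b1, b2) ...
tad_id <- function(n_bins, boundaries) {
  findInterval(seq_len(n_bins) - 1L, c(0L, boundaries))
}

#' Generate one synthetic contact map
#'
#' Builds the intensity `lambda[i, j]` proportional to
#' `(1 + |i - j|)^-decay_exponent`, multiplied by `tad_enrichment` when both
#' bins fall in the same TAD block, normalized so the upper-triangle
#' intensities sum to `read_depth`. Counts are drawn `Poisson(lambda)` on
#' the upper triangle and mirrored (exactly symmetric output); single-cell
#' mode then thins each count `Binomial(count, keep_fraction)`.
#'
#' @param params A [synthetic_params()].
#' @return A [contact_map()] (chromosome label `"chrS"`, resolution 40 kb).
#' @examples
#' m <- generate_map(synthetic_params(n_bins = 64, seed = 7))
#' @export
generate_map <- function(params = synthetic_params()) {
  n <- params$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lambda <- (1 + d)^(-params$decay_exponent)
  tid <- tad_id(n, params$tad_boundaries)
  same_tad <- outer(tid, tid, "==")
  lambda[same_tad] <- lambda[same_tad] * params$tad_enrichment
  ut <- upper.tri(lambda, diag = TRUE)
  lambda <- lambda * (params$read_depth / sum(lambda[ut]))
  with_seed(params$seed, {
    counts <- matrix(0, n, n)
    counts[ut] <- rpois(sum(ut), lambda[ut])
    if (params$mode == "single_cell" && params$keep_fraction < 1) {
      counts[ut] <- rbinom(sum(ut), size = counts[ut],
        prob = params$keep_fraction)
    }
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
    contact_map(counts, chrom = "chrS", resolution = 40000L)
  })
}

#' Generate a paired clean/noisy benchmark set
#'
#' Draws `n_maps` clean synthetic maps and pushes each through the full
#' preprocessing chain — [normalize_unit()], [to_model_range()], then
#' [corrupt()] at every requested noise level — mirroring the two-level
#' benchmark design (noise levels 0.1 and 0.5).
#'
#' @param n_maps Number of clean maps.
#' @param params A [synthetic_params()] template; its seed is replaced by
#'   per-map seeds derived from `seed`.
#' @param sigma_levels Noise levels applied to each map.
#' @param seed Master seed; the whole set is bit-reproducible given it.
#' @param clip_quantile Passed to [normalize_unit()].
#' @param symmetric Draw symmetric noise fields?
#' @return A tibble with one row per (map, sigma): `map_id`, `sigma`,
#'   `clean` (contact_map), `clean_model` (model-range matrix), `noisy`
#'   (corrupted model-range matrix), and seed columns. The generation
#'   manifest (seed, params, levels) is attached as attribute `"manifest"`.
#' @export
make_benchmark_set <- function(n_maps, params = synthetic_params(),
                               sigma_levels = c(0.1, 0.5), seed = 1L,
                               clip_quantile = 0.999, symmetric = FALSE) {
  if (n_maps < 1) abort("`n_maps` must be >= 1.", class = "hicdiffuse_range_error")
  rows <- vector("list", n_maps * length(sigma_levels))
  k <- 1L
  for (i in seq_len(n_maps)) {
    p_i <- params
    p_i$seed <- derive_seed(seed, i)
    cm <- generate_map(p_i)
    y0 <- to_model_range(normalize_unit(cm, clip_quantile = clip_quantile))
    for (s in seq_along(sigma_levels)) {
      noise_seed <- derive_seed(seed, i * 1000L + s)
      x <- corrupt(y0, corruption_spec(sigma_x = sigma_levels[s],
        symmetric = symmetric, seed = noise_seed))
      rows[[k]] <- tibble::tibble(
        map_id = i, sigma = sigma_levels[s],
        clean = list(cm), clean_model = list(unclass(y0)),
        noisy = list(unclass(x)),
        map_seed = p_i$seed, noise_seed = noise_seed
      )
      k <- k + 1L
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "manifest") <- list(
    seed = as.integer(seed), n_maps = as.integer(n_maps),
    sigma_levels = sigma_levels, clip_quantile = clip_quantile,
    symmetric = symmetric,
    params = unclass(params)[setdiff(names(params), "seed")]
  )
  out
}
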