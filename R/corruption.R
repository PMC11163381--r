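#' Specify Gaussian corruption of a model-range map
#'
#' The observation model is `x = y0 + Z` with `Z ~ N(0, sigma_x^2 I)` applied
#' on the `[-1, 1]` model scale (so `sigma_x = 0.1` corresponds to a standard
#' deviation of 0.05 on the `[0, 1]` scale where metrics are computed). With
#' `symmetric = TRUE` the upper triangle of Z (including the diagonal) is
#' drawn and mirrored, so `Z[i, j] == Z[j, i]` while each entry stays
#' marginally `N(0, sigma_x^2)`.
#'
#' @param sigma_x Noise level in `[0, 1]`; 0 adds no noise.
#' @param symmetric Mirror the noise field across the diagonal?
#' @param seed Optional integer seed; corruption is bit-reproducible given it.
#' @export
corruption_spec <- function(sigma_x = 0.1, symmetric = FALSE, seed = NULL) {
  if (!is.numeric(sigma_x) || sigma_x < 0 || sigma_x > 1) {
    abort("`sigma_x` must be in [0, 1].", class = "hicdiffuse_range_error")
  }
  structure(
    list(sigma_x = sigma_x, symmetric = isTRUE(symmetric), seed = seed),
    class = "corruption_spec"
  )
}

#' Corrupt a clean model-range map with Gaussian noise
#'
#' @param y0 Clean matrix in model range.
#' @param spec A [corruption_spec()].
#' @return The noisy observation `x = y0 + Z`, *not* clipped: entries may
#'   leave `[-1, 1]`, matching the observation model.
#' @examples
#' y0 <- matrix(0, 4, 4)
#' x <- corrupt(y0, corruption_spec(sigma_x = 0.1, seed = 1))
#' @export
corrupt <- function(y0, spec = corruption_spec()) {
  if (!inherits(spec, "corruption_spec")) spec <- do.call(corruption_spec, spec)
  v <- unclass(y0)
  if (spec$sigma_x == 0) return(y0)
  n <- nrow(v)
  z <- with_seed(spec$seed, {
    if (spec$symmetric) {
      zz <- matrix(0, n, n)
      ut <- upper.tri(zz, diag = TRUE)
      zz[ut] <- rnorm(sum(ut), sd = spec$sigma_x)
      zz[lower.tri(zz)] <- t(zz)[lower.tri(zz)]
      zz
    } else {
      matrix(rnorm(length(v), sd = spec$sigma_x), n, ncol(v))
    }
  })
  out <- v + z
  attributes(out) <- attributes(y0)
  out
}

#' Cut a matrix into fixed-size tiles
#'
#' The matrix is zero-padded on its bottom/right edges up to a multiple of
#' `tile_size` and cut into non-overlapping tiles in row-major order; the
#' returned plan makes [assemble_tiles()] an exact inverse.
#'
#' @param m Square matrix.
#' @param tile_size Side length of the tiles (64 for the denoising pipeline).
#' @return A list with `tiles` (list of `tile_size x tile_size` matrices) and
#'   `plan` (a `tile_plan` recording size, tile grid and padding).
#' @export
tile_map <- function(m, tile_size = 64L) {
  v <- unclass(m)
  if (tile_size < 1) abort("`tile_size` must be >= 1.",
    class = "hicdiffuse_range_error")
  n <- nrow(v)
  k <- ceiling(n / tile_size)
  pad <- k * tile_size - n
  padded <- matrix(0, n + pad, n + pad)
  padded[seq_len(n), seq_len(n)] <- v
  tiles <- vector("list", k * k)
  idx <- 1L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      rows <- ((i - 1L) * tile_size + 1L):(i * tile_size)
      cols <- ((j - 1L) * tile_size + 1L):(j * tile_size)
      tiles[[idx]] <- padded[rows, cols]
      idx <- idx + 1L
    }
  }
  plan <- structure(
    list(tile_size = as.integer(tile_size), n_tiles_per_side = as.integer(k),
      pad = as.integer(pad), original_n = as.integer(n)),
    class = "tile_plan"
  )
  list(tiles = tiles, plan = plan)
}

#' Reassemble tiles into the full matrix
#'
#' @param tiles List of tiles as produced by [tile_map()], row-major.
#' @param plan The matching `tile_plan`.
#' @return The original `original_n x original_n` matrix, padding removed.
#' @export
assemble_tiles <- function(tiles, plan) {
  k <- plan$n_tiles_per_side
  ts <- plan$tile_size
  if (length(tiles) != k * k) {
    abort(sprintf("expected %d tiles, got %d.", k * k, length(tiles)),
      class = "hicdiffuse_shape_error")
  }
  full <- matrix(0, k * ts, k * ts)
  idx <- 1L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      tl <- tiles[[idx]]
      if (!identical(dim(tl), c(ts, ts)) && !identical(dim(tl), as.integer(c(ts, ts)))) {
        abort(sprintf("tile %d has shape %s, expected %dx%d.",
          idx, paste(dim(tl), collapse = "x"), ts, ts),
          class = "hicdiffuse_shape_error")
      }
      full[((i - 1L) * ts + 1L):(i * ts), ((j - 1L) * ts + 1L):(j * ts)] <- tl
      idx <- idx + 1L
    }
  }
  full[seq_len(plan$original_n), seq_len(plan$original_n), drop = FALSE]
}

#' Crop aligned (clean, noisy) training tiles
#'
#' Tiles are sampled on a regular grid with the given stride (stride equal to
#' `tile_size` gives non-overlapping crops; smaller strides overlap). Pairs
#' whose *clean* tile is entirely zero carry no signal and are dropped when
#' `drop_empty = TRUE`, which matters for sparse single-cell maps.
#'
#' @param clean,noisy Same-shape matrices (clean reference and corrupted
#'   observation, both in model range). "Entirely zero" is judged on the
#'   model scale as all entries equal to the background value (-1 after range
#'   scaling, 0 for raw matrices).
#' @param tile_size Crop side length.
#' @param stride Grid stride in bins.
#' @param drop_empty Drop pairs with constant-background clean tiles?
#' @return A tibble with columns `row`, `col` (0-based top-left corners),
#'   `clean`, `noisy` (list-columns of matrices).
#' @export
crop_training_pairs <- function(clean, noisy, tile_size = 64L, stride = tile_size,
                                drop_empty = TRUE) {
  cv <- unclass(clean); nv <- unclass(noisy)
  assert_same_shape(cv, nv, "clean and noisy maps")
  n <- nrow(cv)
  if (n < tile_size) {
    abort("matrix smaller than `tile_size`.", class = "hicdiffuse_shape_error")
  }
  starts <- seq(1L, n - tile_size + 1L, by = stride)
  background <- if (min(cv) >= 0) 0 else -1
  grid <- expand.grid(row = starts, col = starts)
  keep_clean <- vector("list", nrow(grid))
  keep_noisy <- vector("list", nrow(grid))
  nonempty <- logical(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    r <- grid$row[g]; cc <- grid$col[g]
    ct <- cv[r:(r + tile_size - 1L), cc:(cc + tile_size - 1L)]
    keep_clean[[g]] <- ct
    keep_noisy[[g]] <- nv[r:(r + tile_size - 1L), cc:(cc + tile_size - 1L)]
    nonempty[g] <- any(ct != background)
  }
  out <- tibble::tibble(
    row = as.integer(grid$row - 1L),
    col = as.integer(grid$col - 1L),
    clean = keep_clean,
    noisy = keep_noisy
  )
  if (drop_empty) out <- out[nonempty, , drop = FALSE]
  out
}
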