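#' Construct a Hi-C contact map
#'
#' A contact map is a square, non-negative matrix of read counts between
#' genomic bins of one chromosome, together with the chromosome label and the
#' bin width. Symmetry is recorded rather than assumed: corrupted maps can be
#' asymmetric, and downstream code inspects the flag instead of silently
#' symmetrizing.
#'
#' @param values Square numeric matrix of non-negative contact counts.
#' @param chrom Chromosome identifier, e.g. `"chr1"`.
#' @param resolution Bin width in base pairs.
#' @param tol Tolerance used to decide whether `values` is symmetric.
#' @return An object of class `contact_map` with fields `values`, `chrom`,
#'   `resolution`, `n_bins` and `symmetric`.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 5
#' contact_map(m, "chr1", 40000L)
#' @export
contact_map <- function(values, chrom = "chr1", resolution = 40000L, tol = 1e-9) {
  values <- as.matrix(values)
  if (!is_square_matrix(values)) {
    abort("`values` must be a square matrix.", class = "hicdiffuse_shape_error")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("contact counts must be finite and non-negative.",
      class = "hicdiffuse_range_error")
  }
  structure(
    list(
      values = unname(values),
      chrom = as.character(chrom),
      resolution = as.integer(resolution),
      n_bins = nrow(values),
      symmetric = max(abs(values - t(values))) <= tol
    ),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> %s @ %s bp: %d x %d bins, %s counts in [%g, %g], %s\n",
    x$chrom, format(x$resolution, big.mark = ","), x$n_bins, x$n_bins,
    format(sum(x$values[upper.tri(x$values, diag = TRUE)]), big.mark = ","),
    min(x$values), max(x$values),
    if (x$symmetric) "symmetric" else "asymmetric"
  ))
  invisible(x)
}

#' @export
dim.contact_map <- function(x) dim(x$values)

#' Tidy a contact map into a long tibble
#'
#' One row per matrix entry of the upper triangle (including the diagonal),
#' with genomic start coordinates, handy for ggplot2.
#'
#' @param x A [contact_map()].
#' @param ... Unused.
#' @export
tidy.contact_map <- function(x, ...) {
  idx <- which(upper.tri(x$values, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    chrom = x$chrom,
    bin1 = idx[, 1] - 1L,
    bin2 = idx[, 2] - 1L,
    start1 = (idx[, 1] - 1L) * x$resolution,
    start2 = (idx[, 2] - 1L) * x$resolution,
    count = x$values[idx]
  )
}

#' Heatmap of a contact map
#'
#' Plots `log10(1 + count)` so the distance decay over several orders of
#' magnitude stays visible.
#'
#' @param object A [contact_map()], or a plain square matrix.
#' @param ... Unused.
#' @export
autoplot.contact_map <- function(object, ...) {
  v <- if (inherits(object, "contact_map")) object$values else object
  df <- expand.grid(bin1 = seq_len(nrow(v)), bin2 = seq_len(ncol(v)))
  df$value <- log10(1 + as.vector(v))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin2, y = .data$bin1,
      fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
      name = "log10(1+n)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL

#' Normalize a contact map into the unit range
#'
#' Entries are clipped at the `clip_quantile` quantile of the *nonzero* counts
#' and divided by the clip value. `clip_quantile = 1` is plain max-division;
#' the default 0.999 tames single extreme outliers, which otherwise compress
#' the whole dynamic range (standard practice in Hi-C map enhancement). The
#' clip value is stored so the scaling can be undone for unclipped entries.
#'
#' @param m A [contact_map()] or a non-negative square matrix.
#' @param clip_quantile Quantile (in (0, 1]) of nonzero entries at which to
#'   clip before dividing.
#' @return A `unit_map`: a matrix with entries in `[0, 1]` carrying attributes
#'   `clip_value` and `clip_quantile`.
#' @examples
#' m <- contact_map(matrix(c(0, 10, 10, 0), 2), "chr1", 40000)
#' normalize_unit(m, clip_quantile = 1)
#' @export
normalize_unit <- function(m, clip_quantile = 0.999) {
  v <- if (inherits(m, "contact_map")) m$values else as.matrix(m)
  if (any(v < 0)) {
    abort("normalize_unit() expects non-negative counts.",
      class = "hicdiffuse_range_error")
  }
  if (clip_quantile <= 0 || clip_quantile > 1) {
    abort("`clip_quantile` must be in (0, 1].", class = "hicdiffuse_range_error")
  }
  nz <- v[v > 0]
  if (length(nz) == 0L) {
    clip <- 1
    out <- v
  } else {
    clip <- as.numeric(quantile(nz, clip_quantile, names = FALSE, type = 7))
    if (clip <= 0) clip <- max(nz)
    out <- pmin(v, clip) / clip
  }
  structure(out, clip_value = clip, clip_quantile = clip_quantile,
    class = c("unit_map", class(matrix())))
}

#' Rescale a unit-range map to the diffusion model range
#'
#' Applies `y = 2 * u - 1` entrywise; the diffusion process operates on data
#' nominally in `[-1, 1]`.
#'
#' @param u Matrix with entries in `[0, 1]` (a `unit_map` or plain matrix).
#' @param tol Tolerance for the range check.
#' @return A `model_map` matrix with entries in `[-1, 1]`, carrying over any
#'   normalization provenance attributes.
#' @export
to_model_range <- function(u, tol = 1e-9) {
  v <- unclass(u)
  if (any(v < -tol) || any(v > 1 + tol)) {
    abort("to_model_range() expects entries in [0, 1].",
      class = "hicdiffuse_range_error")
  }
  out <- 2 * v - 1
  attr(out, "clip_value") <- attr(u, "clip_value", exact = TRUE)
  class(out) <- c("model_map", class(matrix()))
  out
}

#' Rescale model-range data back to the unit range
#'
#' Applies `u = (y + 1) / 2`. Denoised outputs can stray outside `[-1, 1]`;
#' with `clip = TRUE` (required before SSIM/HiCRep, which expect non-negative
#' inputs) the result is clamped into `[0, 1]`.
#'
#' @param m Matrix in model range (entries nominally in `[-1, 1]`).
#' @param clip Clamp the result into `[0, 1]`?
#' @return A `unit_map` matrix.
#' @export
from_model_range <- function(m, clip = TRUE) {
  out <- (unclass(m) + 1) / 2
  if (clip) out <- pmin(pmax(out, 0), 1)
  attr(out, "clip_value") <- attr(m, "clip_value", exact = TRUE)
  class(out) <- c("unit_map", class(matrix()))
  out
}
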