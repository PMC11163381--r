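#' Read a contact matrix from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`dense`}{Whitespace-delimited square matrix, one row per line.}
#'   \item{`coo`}{Tab-separated pixel table with header
#'     `chrom  bin1  bin2  count` (0-based bins). May hold several
#'     chromosomes; `chrom` selects one and unknown labels raise an error
#'     listing what is present. Only the upper triangle needs to be stored;
#'     the matrix is filled symmetrically.}
#'   \item{`mtx`}{MatrixMarket sparse format (read via the Matrix package),
#'     upper triangle or full.}
#' }
#' Intra-chromosomal maps only; missing bins are zero-filled.
#'
#' @param path File to read.
#' @param chrom Chromosome to extract (required for `coo` files; label for
#'   the others).
#' @param resolution Bin width in base pairs recorded on the result.
#' @param format One of `"auto"`, `"dense"`, `"coo"`, `"mtx"`. `"auto"` picks
#'   by file extension (`.tsv`/`.coo` -> coo, `.mtx` -> mtx, else dense).
#' @param n_bins Optional matrix size for sparse inputs whose trailing bins
#'   are empty.
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, chrom = "chr1", resolution = 40000L,
                             format = c("auto", "dense", "coo", "mtx"),
                             n_bins = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "hicdiffuse_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "coo", coo = "coo", mtx = "mtx", "dense")
  }
  values <- switch(format,
    dense = {
      v <- as.matrix(read.table(path, header = FALSE))
      dimnames(v) <- NULL
      if (nrow(v) != ncol(v)) {
        abort(sprintf("dense matrix in %s is %d x %d, not square.",
          path, nrow(v), ncol(v)), class = "hicdiffuse_shape_error")
      }
      v
    },
    coo = {
      px <- read.table(path, header = TRUE, sep = "\t",
        colClasses = c("character", "integer", "integer", "numeric"))
      names(px) <- c("chrom", "bin1", "bin2", "count")
      have <- unique(px$chrom)
      if (!chrom %in% have) {
        abort(
          sprintf("chromosome '%s' not in file; available: %s",
            chrom, paste(have, collapse = ", ")),
          class = "hicdiffuse_chrom_error"
        )
      }
      px <- px[px$chrom == chrom, , drop = FALSE]
      n <- n_bins %||% (max(px$bin1, px$bin2) + 1L)
      v <- matrix(0, n, n)
      v[cbind(px$bin1 + 1L, px$bin2 + 1L)] <- px$count
      v[cbind(px$bin2 + 1L, px$bin1 + 1L)] <- px$count
      v
    },
    mtx = {
      sm <- Matrix::readMM(path)
      n <- n_bins %||% max(dim(sm))
      v <- matrix(0, n, n)
      sm <- methods::as(sm, "TsparseMatrix")
      i <- sm@i + 1L; j <- sm@j + 1L; xval <- sm@x
      v[cbind(i, j)] <- xval
      v[cbind(j, i)] <- xval
      v
    }
  )
  contact_map(values, chrom = chrom, resolution = resolution)
}

#' Write a contact matrix to disk
#'
#' Inverse of [read_contact_map()]; `coo` stores the upper triangle
#' (including the diagonal) of nonzero entries.
#'
#' @param m A [contact_map()] or square matrix.
#' @param path Output file.
#' @param format `"dense"`, `"coo"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(m, path, format = c("dense", "coo", "mtx")) {
  format <- match.arg(format)
  v <- if (inherits(m, "contact_map")) m$values else as.matrix(m)
  chrom <- if (inherits(m, "contact_map")) m$chrom else "chr1"
  switch(format,
    dense = write.table(v, path, row.names = FALSE, col.names = FALSE),
    coo = {
      keep <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
      px <- data.frame(
        chrom = chrom,
        bin1 = keep[, 1] - 1L,
        bin2 = keep[, 2] - 1L,
        count = v[keep]
      )
      px <- px[order(px$bin1, px$bin2), , drop = FALSE]
      write.table(px, path, sep = "\t", row.names = FALSE, quote = FALSE)
    },
    mtx = {
      ut <- v
      ut[lower.tri(ut)] <- 0
      Matrix::writeMM(methods::as(Matrix::Matrix(ut, sparse = TRUE), "TsparseMatrix"), path)
    }
  )
  invisible(path)
}
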