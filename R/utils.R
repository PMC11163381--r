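# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. `seed = NULL` leaves the global stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "hicdiffuse_range_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed; keeps results < 2^31 so R accepts them.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 104729 * as.double(k)) %% 2147483629) + 1L
}

is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

assert_same_shape <- function(a, b, what = "matrices") {
  if (!identical(dim(a), dim(b))) {
    abort(
      sprintf(
        "%s must have identical shape (got %s vs %s).",
        what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")
      ),
      class = "hicdiffuse_shape_error"
    )
  }
  invisible(TRUE)
}

# Map over the leaves (numeric arrays) of a nested parameter list.
param_map <- function(p, f) {
  if (is.list(p)) return(lapply(p, param_map, f = f))
  f(p)
}

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    return(mapply(param_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  }
  f(a, b)
}

param_sum <- function(p, f) {
  if (is.list(p)) return(sum(vapply(p, param_sum, numeric(1), f = f)))
  f(p)
}

param_flatten <- function(p) {
  if (!is.list(p)) return(list(p))
  unlist(lapply(p, param_flatten), recursive = FALSE, use.names = FALSE)
}
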