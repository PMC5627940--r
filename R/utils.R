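#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm sd t.test fft coef lm
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

assert_scalar_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

check_square_matrix <- function(W, name = "W") {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    abort(sprintf("`%s` must be a square matrix (got %d x %d).",
                  name, NROW(W), NCOL(W)))
  }
  bad <- which(!is.finite(W), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("`%s` has a non-finite entry at row %d, column %d.",
                  name, bad[1, 1], bad[1, 2]))
  }
  neg <- which(W < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("`%s` has a negative entry at row %d, column %d.",
                  name, neg[1, 1], neg[1, 2]))
  }
  invisible(W)
}

# derived sub-seed, kept inside 32-bit integer range
derive_seed <- function(base, run, cycle = 0L, offset = 0L) {
  ((as.double(base) + run) * 1009 + cycle + offset) %% 2147483647
}
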