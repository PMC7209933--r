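# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# random-number stream.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Draw n rows from a multivariate normal with zero mean and correlation
# matrix R, via the eigendecomposition (tolerant of semi-definite R, e.g.
# duplicated items).
rmvnorm_chol <- function(n, R) {
  p <- ncol(R)
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(ev), p)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% t(L)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_numeric <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric with no missing values", what),
         call. = FALSE)
  }
  invisible(x)
}
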