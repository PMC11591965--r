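`%||%` <- function(x, y) if (is.null(x)) y else x

stop_nd <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_nd(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper)
    stop_nd(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stop_nd(sprintf("'%s' must be an integer", name))
  invisible(as.integer(x))
}

# Run code with the RNG seeded, restoring the caller's RNG state afterwards.
# All randomized operations in the package funnel through this so that a
# user-level seed makes a whole analysis reproducible.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Symmetric-matrix validation used by several constructors.
check_symmetric <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_nd(sprintf("'%s' must be a square matrix", name))
  if (max(abs(m - t(m))) > tol)
    stop_nd(sprintf("'%s' must be symmetric", name))
  invisible(m)
}
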