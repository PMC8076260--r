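#' Evaluate an expression under a local RNG state
#'
#' Sets the RNG to a reproducible state derived from `seed`, evaluates
#' `expr`, and restores the caller's RNG state afterwards. All stochastic
#' operations in the package run through this helper so that every output
#' is a pure function of its declared seed and the global RNG stream is
#' never disturbed.
#'
#' @param seed integer seed (kept below 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a master seed and a stage label; deterministic,
# stays within 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# Wrap angles in degrees onto the principal branch (-180, 180].
wrap_deg <- function(p) {
  p <- ((p + 180) %% 360) - 180
  p[p <= -180] <- p[p <= -180] + 360
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%g, %g]", name, lower, upper))
  invisible(x)
}
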