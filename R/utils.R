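# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so package functions never perturb user randomness.
#' A `NULL` seed evaluates `code` under the current RNG state.
#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# log(1 + exp(-t)) evaluated without overflow for large |t|:
# equals max(-t, 0) + log(1 + exp(-|t|)).
log1pexp_neg <- function(t) {
  pmax(-t, 0) + log1p(exp(-abs(t)))
}

# Column standardization with a floor on the scale so constant genes do not
# produce divisions by zero.  Returns list(x, center, scale).
standardize_columns <- function(x, center = NULL, scale = NULL,
                                scale_floor = 1e-12) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2L, stats::sd)
    scale <- pmax(scale, scale_floor)
  }
  xs <- sweep(x, 2L, center, "-")
  xs <- sweep(xs, 2L, scale, "/")
  list(x = xs, center = center, scale = scale)
}

row_norms2 <- function(w) sqrt(rowSums(w^2))

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    stop(sprintf("'%s' must be a single number strictly between 0 and 1", name),
         call. = FALSE)
  invisible(x)
}
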