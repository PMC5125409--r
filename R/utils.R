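# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
abort_artic <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Deterministic rounding (half away from zero)
#'
#' Frame-count arithmetic must not depend on banker's rounding.
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Run code with a private RNG stream
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb
#' the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Column-wise variance with an explicit denominator
#' @noRd
col_var <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  colSums((x - rep(mu, each = n))^2) / (n - 1L)
}

#' Check a numeric scalar
#' @noRd
check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_artic("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    abort_artic("'%s' must be positive", name)
  invisible(x)
}
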