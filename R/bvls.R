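# Bounded-variable least squares: min ||Ax - b||^2 subject to l <= x <= u.
#
# Active-set method in the Stark--Parker style.  The problems solved here
# are tiny (<= 10 unknowns per frame), so the emphasis is on exactness:
# at convergence the KKT conditions hold and the solution matches ordinary
# least squares whenever the unconstrained optimum is interior.  A 1e-12
# ridge breaks ties toward the smallest-norm solution on rank-deficient
# systems.

#' Bounded linear least squares
#'
#' Solves `min ||A x - b||^2` subject to `lower <= x <= upper` by a primal
#' active-set method.  This is the numerical core of model inversion: each
#' frame's articulatory parameters are the bounded least-squares fit of the
#' model loadings to the observed sensor coordinates.
#'
#' @param A numeric matrix `(m, n)`.
#' @param b numeric vector of length `m`.
#' @param lower,upper bound vectors (recycled to length `n`).
#' @param ridge small diagonal regularization added to the normal
#'   equations; breaks ties toward the smallest norm (default 1e-12).
#' @param max_iter iteration cap (default `30 * n + 30`).
#' @return List with `x` (solution), `residual` (`||Ax - b||`), and
#'   `iterations`.
#' @export
bvls <- function(A, b, lower = -3, upper = 3, ridge = 1e-12,
                 max_iter = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  if (length(b) != m) abort_artic("length(b) must equal nrow(A)")
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(lower > upper)) abort_artic("lower bound exceeds upper bound")
  max_iter <- max_iter %||% (30L * n + 30L)
  AtA <- crossprod(A) + diag(ridge, n)
  Atb <- as.vector(crossprod(A, b))
  x <- pmin(pmax(numeric(n), lower), upper)
  # state: 0 free, -1 at lower, +1 at upper; start all free
  state <- integer(n)
  tol <- 1e-10
  solve_free <- function(state, x) {
    free <- which(state == 0L)
    xf <- x
    xf[state == -1L] <- lower[state == -1L]
    xf[state == 1L] <- upper[state == 1L]
    if (length(free)) {
      rhs <- if (length(free) == n) Atb
      else Atb[free] - as.vector(AtA[free, -free, drop = FALSE] %*% xf[-free])
      xf[free] <- solve(AtA[free, free, drop = FALSE], rhs)
    }
    xf
  }
  for (iter in seq_len(max_iter)) {
    z <- solve_free(state, x)
    free <- which(state == 0L)
    viol <- free[z[free] < lower[free] - tol | z[free] > upper[free] + tol]
    if (length(viol)) {
      # step from x toward z until the first bound is hit
      alpha <- 1
      hit <- 0L; hit_side <- 0L
      for (j in free) {
        dj <- z[j] - x[j]
        if (dj < -tol && z[j] < lower[j]) {
          a <- (lower[j] - x[j]) / dj
          if (a < alpha) { alpha <- a; hit <- j; hit_side <- -1L }
        } else if (dj > tol && z[j] > upper[j]) {
          a <- (upper[j] - x[j]) / dj
          if (a < alpha) { alpha <- a; hit <- j; hit_side <- 1L }
        }
      }
      x <- x + alpha * (z - x)
      if (hit > 0L) {
        state[hit] <- hit_side
        x[hit] <- if (hit_side < 0L) lower[hit] else upper[hit]
      }
      next
    }
    x <- z
    # KKT: gradient g = AtA x - Atb; free vars have g = 0 by construction;
    # a lower-bound var is optimal iff g >= 0, an upper-bound var iff
    # g <= 0 -- free the worst violator
    g <- as.vector(AtA %*% x) - Atb
    worst <- 0; worst_j <- 0L
    for (j in which(state != 0L)) {
      v <- if (state[j] == -1L) g[j] else -g[j]
      if (v < worst) { worst <- v; worst_j <- j }
    }
    if (worst_j == 0L || worst > -tol) {
      return(list(x = as.vector(x),
                  residual = sqrt(sum((A %*% x - b)^2)),
                  iterations = iter))
    }
    state[worst_j] <- 0L
  }
  abort_artic("bvls failed to converge in %d iterations (residual %.3g)",
              max_iter, sqrt(sum((A %*% x - b)^2)))
}
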