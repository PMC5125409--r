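# Articulatory parameter trajectories: a (parameters x frames) matrix at a
# fixed frame rate.  Parameter values are in score standard-deviation units,
# so the inversion box [-3, 3] means +/- 3 SD for every parameter.

#' Create a trajectory matrix
#'
#' @param values numeric matrix, parameters in rows, frames in columns.
#' @param rate frame rate in Hz.
#' @param parameter_names optional row names; defaults to existing row names
#'   or `p1, p2, ...`.
#' @return An object of class `trajectory_matrix`.
#' @export
trajectory_matrix <- function(values, rate, parameter_names = NULL) {
  values <- as.matrix(values)
  check_scalar(rate, "rate", positive = TRUE)
  if (!is.numeric(values) || (length(values) && any(!is.finite(values))))
    abort_artic("trajectory values must be finite numbers")
  if (is.null(parameter_names))
    parameter_names <- rownames(values) %||% paste0("p", seq_len(nrow(values)))
  if (length(parameter_names) != nrow(values))
    abort_artic("need one parameter name per row (%d names, %d rows)",
                length(parameter_names), nrow(values))
  rownames(values) <- parameter_names
  structure(values, rate = rate, class = c("trajectory_matrix", "matrix", "array"))
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("Trajectory matrix: %d parameters x %d frames @ %g Hz (%.3f s)\n",
              nrow(x), ncol(x), traj_rate(x), ncol(x) / traj_rate(x)))
  cat("  parameters:", paste(rownames(x), collapse = ", "), "\n")
  if (ncol(x)) {
    rng <- range(x)
    cat(sprintf("  value range: [%.3f, %.3f]\n", rng[1L], rng[2L]))
  }
  invisible(x)
}

#' @export
plot.trajectory_matrix <- function(x, ...) {
  t <- (seq_len(ncol(x)) - 1L) / traj_rate(x)
  graphics::matplot(t, t(unclass(x)), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "parameter value (SD units)", ...)
  graphics::legend("topright", legend = rownames(x), col = seq_len(nrow(x)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' Frame rate of a trajectory matrix
#' @param x a `trajectory_matrix`.
#' @return Rate in Hz.
#' @export
traj_rate <- function(x) attr(x, "rate")

#' Extract a frame slice of a trajectory matrix
#' @param x a `trajectory_matrix`.
#' @param frames integer indices of frames to keep (1-based).
#' @return A `trajectory_matrix` with the selected frames.
#' @export
traj_slice <- function(x, frames) {
  trajectory_matrix(unclass(x)[, frames, drop = FALSE], traj_rate(x),
                    rownames(x))
}

#' Write a trajectory matrix as CSV
#'
#' One row per frame; the first column is the frame time in seconds, the
#' remaining columns are the parameters.
#'
#' @param traj a [trajectory_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  t <- (seq_len(ncol(traj)) - 1L) / traj_rate(traj)
  df <- data.frame(time = t, t(unclass(traj)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory matrix from CSV
#'
#' @param path CSV written by [write_trajectory()] (first column time,
#'   remaining columns parameters).
#' @return A [trajectory_matrix()]; the rate is inferred from the time
#'   column spacing.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L)
    abort_artic("trajectory CSV must have a time column and >= 1 parameter")
  t <- df[[1L]]
  if (length(t) < 2L)
    abort_artic("trajectory CSV must contain >= 2 frames to infer the rate")
  dt <- diff(t)
  if (max(abs(dt - dt[1L])) > 1e-6)
    abort_artic("trajectory CSV times are not uniformly spaced")
  trajectory_matrix(t(as.matrix(df[, -1L, drop = FALSE])), rate = 1 / dt[1L],
                    parameter_names = names(df)[-1L])
}
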