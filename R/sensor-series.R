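# Sensor frame series: timestamped 3-D positions of named sensors recorded
# at a uniform rate, with an explicit missing-data mask (TRUE = visible).

#' Create a sensor frame series
#'
#' The raw and head-corrected representation of a recording: positions of
#' named sensors (mm) at uniformly spaced times.  Missing samples are
#' carried as an explicit per-sensor-per-frame mask, never as disguised
#' `NA`s inside computations.
#'
#' @param positions numeric array `(frames, sensors, 3)` in mm.
#' @param rate sampling rate in Hz.
#' @param sensor_names character vector, one name per sensor.
#' @param times optional frame times in seconds; defaults to
#'   `(0:(frames-1))/rate`.  Must be uniform at `rate`.
#' @param mask logical matrix `(frames, sensors)`, `TRUE` where the sample
#'   is valid; defaults to all `TRUE`.
#' @return An object of class `sensor_series`.
#' @export
sensor_series <- function(positions, rate, sensor_names,
                          times = NULL, mask = NULL) {
  check_scalar(rate, "rate", positive = TRUE)
  positions <- unclass(positions)
  d <- dim(positions)
  if (length(d) != 3L || d[3L] != 3L)
    abort_artic("'positions' must be a (frames x sensors x 3) array")
  n <- d[1L]; s <- d[2L]
  if (length(sensor_names) != s)
    abort_artic("need %d sensor names, got %d", s, length(sensor_names))
  if (anyDuplicated(sensor_names))
    abort_artic("sensor names must be unique")
  if (is.null(times)) times <- (seq_len(n) - 1L) / rate
  if (length(times) != n)
    abort_artic("need one time per frame")
  if (n > 1L && max(abs(diff(times) - 1 / rate)) > 1e-9)
    abort_artic("times are not uniform at %g Hz within 1e-9 s", rate)
  if (is.null(mask)) mask <- matrix(TRUE, n, s)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    abort_artic("'mask' must be a logical (frames x sensors) matrix")
  if (any(!is.finite(positions[rep(mask, 3L)])))
    abort_artic("positions must be finite wherever the mask is TRUE")
  dimnames(positions) <- list(NULL, sensor_names, c("x", "y", "z"))
  structure(list(sensor_names = as.character(sensor_names),
                 times = as.numeric(times),
                 positions = positions, mask = mask, rate = rate),
            class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  n <- n_frames(x)
  cat(sprintf("Sensor series: %d sensors x %d frames @ %g Hz (%.3f s)\n",
              length(x$sensor_names), n, x$rate,
              if (n) n / x$rate else 0))
  cat("  sensors:", paste(x$sensor_names, collapse = ", "), "\n")
  miss <- sum(!x$mask)
  if (miss > 0)
    cat(sprintf("  missing samples: %d (%.2f%%)\n", miss,
                100 * miss / length(x$mask)))
  invisible(x)
}

#' Number of frames in a sensor series
#' @param series a `sensor_series`.
#' @return Integer frame count.
#' @export
n_frames <- function(series) dim(series$positions)[1L]

#' Flatten a sensor series to a frames x coordinates matrix
#'
#' Coordinates are stacked sensor-major: `sensor.x, sensor.y, sensor.z` for
#' each sensor in order, giving the column names used by extraction-scheme
#' subsets.
#' @param series a `sensor_series`.
#' @param sensors optional subset of sensor names.
#' @return Numeric matrix `(frames, 3 * sensors)` with named columns.
#' @export
series_matrix <- function(series, sensors = NULL) {
  sensors <- sensors %||% series$sensor_names
  idx <- match(sensors, series$sensor_names)
  if (anyNA(idx))
    abort_artic("unknown sensors: %s",
                paste(sensors[is.na(idx)], collapse = ", "))
  n <- n_frames(series)
  out <- matrix(0, n, 3L * length(idx))
  for (j in seq_along(idx))
    out[, 3L * j - 2:0] <- series$positions[, idx[j], , drop = FALSE]
  colnames(out) <- coord_names(sensors)
  out
}

#' Coordinate names for a set of sensors
#' @param sensors character vector of sensor names.
#' @return Character vector `sensor.x, sensor.y, sensor.z` per sensor.
#' @export
coord_names <- function(sensors) {
  as.vector(t(outer(sensors, c("x", "y", "z"), paste, sep = ".")))
}

#' Rebuild a sensor series from a flat coordinate matrix
#' @param mat matrix `(frames, 3 * sensors)` as produced by [series_matrix()].
#' @param rate sampling rate in Hz.
#' @param sensor_names sensor names (columns of `mat` must be their
#'   coordinates in order).
#' @param times,mask as in [sensor_series()].
#' @return A [sensor_series()].
#' @export
matrix_to_series <- function(mat, rate, sensor_names, times = NULL,
                             mask = NULL) {
  n <- nrow(mat)
  s <- length(sensor_names)
  if (ncol(mat) != 3L * s)
    abort_artic("matrix has %d columns; expected %d", ncol(mat), 3L * s)
  pos <- array(0, c(n, s, 3L))
  for (j in seq_len(s)) pos[, j, ] <- mat[, 3L * j - 2:0]
  sensor_series(pos, rate, sensor_names, times = times, mask = mask)
}

#' Select sensors from a series
#' @param series a `sensor_series`.
#' @param sensors names to keep, in the requested order.
#' @return A `sensor_series` with the selected sensors.
#' @export
select_sensors <- function(series, sensors) {
  idx <- match(sensors, series$sensor_names)
  if (anyNA(idx))
    abort_artic("unknown sensors: %s",
                paste(sensors[is.na(idx)], collapse = ", "))
  sensor_series(series$positions[, idx, , drop = FALSE], series$rate,
                sensors, times = series$times,
                mask = series$mask[, idx, drop = FALSE])
}
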