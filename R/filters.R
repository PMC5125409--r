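# Zero-phase low-pass filtering, resampling and stream synchronization.
#
# All filtering is forward-backward (zero phase): causal filtering would
# delay articulation relative to the audio it must stay synchronous with.

# Minimum series length accepted by the zero-phase filter, in samples.
min_filter_length <- function(order) 3L * (2L * order + 1L)

#' Low-pass filter the columns of a matrix, zero phase
#' @noRd
lowpass_cols <- function(mat, rate, cutoff, order) {
  if (rate <= 2 * cutoff)
    abort_artic("sampling rate (%g Hz) must exceed twice the cutoff (%g Hz)",
                rate, cutoff)
  n <- nrow(mat)
  if (n < min_filter_length(order))
    abort_artic(paste0("series too short for the order-%d filter: ",
                       "%d samples, need at least %d"),
                order, n, min_filter_length(order))
  bw <- signal::butter(order, cutoff / (rate / 2))
  # mirror-pad (odd extension) and remove the mean before the
  # forward-backward pass: keeps DC exact and confines edge transients
  # to the padding
  p <- min(n - 1L, 120L)
  apply(mat, 2L, function(col) {
    ext <- c(2 * col[1L] - col[(p + 1L):2L], col,
             2 * col[n] - col[(n - 1L):(n - p)])
    mu <- mean(ext)
    y <- signal::filtfilt(bw, ext - mu) + mu
    y[(p + 1L):(p + n)]
  })
}

#' Linearly interpolate masked gaps in one channel
#' @noRd
fill_gaps <- function(x, visible) {
  if (all(visible)) return(x)
  if (!any(visible))
    abort_artic("a sensor channel has no visible samples")
  idx <- seq_along(x)
  stats::approx(idx[visible], x[visible], xout = idx, rule = 2)$y
}

#' Low-pass filter a sensor series in place (no rate change)
#'
#' Masked gaps are linearly interpolated before filtering and re-masked
#' afterwards; the mask is unchanged.
#'
#' @param series a [sensor_series()].
#' @param cutoff low-pass cutoff in Hz.
#' @param order Butterworth order.
#' @return A filtered [sensor_series()] at the original rate.
#' @export
lowpass_series <- function(series, cutoff = 20, order = 6) {
  mat <- series_matrix(series)
  vis <- series$mask[, rep(seq_along(series$sensor_names), each = 3L),
                     drop = FALSE]
  for (j in seq_len(ncol(mat))) mat[, j] <- fill_gaps(mat[, j], vis[, j])
  mat <- lowpass_cols(mat, series$rate, cutoff, order)
  matrix_to_series(mat, series$rate, series$sensor_names,
                   times = series$times, mask = series$mask)
}

#' Resample a sensor series to a lower rate with anti-alias filtering
#'
#' The series is zero-phase low-pass filtered at `cutoff` (Butterworth,
#' `order`) at its native rate, then linearly interpolated onto a uniform
#' grid at `target_rate` starting at the first frame time.  DC is preserved
#' exactly; content above the cutoff is strongly attenuated.  Masked gaps
#' are linearly interpolated before filtering and the output frames whose
#' neighbouring source samples were missing are re-masked.
#'
#' @param series a [sensor_series()] (e.g. EMA at 100 Hz).
#' @param target_rate output rate in Hz (default 60).
#' @param cutoff anti-alias cutoff in Hz (default 20).
#' @param order Butterworth order (default 6).
#' @return A [sensor_series()] at `target_rate`.
#' @export
resample_lowpass <- function(series, target_rate = 60, cutoff = 20,
                             order = 6) {
  check_scalar(target_rate, "target_rate", positive = TRUE)
  filtered <- lowpass_series(series, cutoff = cutoff, order = order)
  t_out <- seq(series$times[1L],
               series$times[n_frames(series)] + 1e-9, by = 1 / target_rate)
  interp_series(filtered, t_out, target_rate)
}

#' Linearly interpolate a series onto explicit output times
#' @noRd
interp_series <- function(series, t_out, rate_out) {
  mat <- series_matrix(series)
  vis <- series$mask[, rep(seq_along(series$sensor_names), each = 3L),
                     drop = FALSE]
  n_out <- length(t_out)
  out <- matrix(0, n_out, ncol(mat))
  okm <- matrix(TRUE, n_out, length(series$sensor_names))
  for (j in seq_len(ncol(mat))) {
    filled <- fill_gaps(mat[, j], vis[, j])
    out[, j] <- stats::approx(series$times, filled, xout = t_out, rule = 2)$y
  }
  # an output frame is visible only if the source samples around it were
  for (s in seq_along(series$sensor_names)) {
    v <- stats::approx(series$times, as.numeric(series$mask[, s]),
                       xout = t_out, rule = 2)$y
    okm[, s] <- v > 1 - 1e-9
  }
  matrix_to_series(out, rate_out, series$sensor_names, times = t_out,
                   mask = okm)
}

#' Synchronize an EMA stream onto the motion-capture clock
#'
#' The two devices share a clock but sample at different rates (EMA
#' typically 100 Hz, mocap 60 Hz).  The EMA stream is optionally low-pass
#' filtered at its native rate (anti-aliasing before the implicit
#' downsampling), then its values are linearly interpolated between
#' consecutive EMA frames at each mocap timestamp.  The result is a single
#' series containing the mocap sensors followed by the EMA sensors, on the
#' mocap clock.  With `cutoff = NULL` no filtering is applied and EMA
#' samples that fall exactly on a mocap timestamp pass through unchanged.
#'
#' @param ema [sensor_series()] for the EMA stream.
#' @param mocap [sensor_series()] for the mocap stream.
#' @param cutoff anti-alias cutoff in Hz applied to `ema`, or `NULL` for
#'   pure interpolation (default 20).
#' @param order Butterworth order for the anti-alias filter.
#' @return A merged [sensor_series()] at the mocap rate, restricted to the
#'   overlap of the two time ranges.
#' @export
synchronize <- function(ema, mocap, cutoff = 20, order = 6) {
  if (length(intersect(ema$sensor_names, mocap$sensor_names)))
    abort_artic("streams share sensor names: %s",
                paste(intersect(ema$sensor_names, mocap$sensor_names),
                      collapse = ", "))
  t0 <- max(ema$times[1L], mocap$times[1L])
  t1 <- min(ema$times[length(ema$times)], mocap$times[length(mocap$times)])
  if (t0 > t1 + 1e-9)
    abort_artic("streams do not overlap in time ([%g, %g] vs [%g, %g])",
                ema$times[1L], ema$times[length(ema$times)],
                mocap$times[1L], mocap$times[length(mocap$times)])
  keep <- which(mocap$times >= t0 - 1e-9 & mocap$times <= t1 + 1e-9)
  mo <- sensor_series(mocap$positions[keep, , , drop = FALSE], mocap$rate,
                      mocap$sensor_names, times = mocap$times[keep],
                      mask = mocap$mask[keep, , drop = FALSE])
  if (!is.null(cutoff)) ema <- lowpass_series(ema, cutoff, order)
  emai <- interp_series(ema, mo$times, mocap$rate)
  pos <- array(0, c(n_frames(mo), length(mo$sensor_names) +
                      length(emai$sensor_names), 3L))
  pos[, seq_along(mo$sensor_names), ] <- mo$positions
  pos[, length(mo$sensor_names) + seq_along(emai$sensor_names), ] <-
    emai$positions
  sensor_series(pos, mocap$rate, c(mo$sensor_names, emai$sensor_names),
                times = mo$times, mask = cbind(mo$mask, emai$mask))
}

#' Smooth articulatory trajectories with a zero-phase Butterworth filter
#'
#' A 6th-order 8 Hz low-pass removes measurement noise from inverted
#' parameter trajectories while leaving the articulation band untouched.
#' Applied forward-backward, so DC and phase are preserved.  Values pushed
#' outside the inversion box by the filter are re-clipped.
#'
#' @param traj a [trajectory_matrix()].
#' @param order Butterworth order (default 6).
#' @param cutoff cutoff frequency in Hz (default 8).
#' @param bounds length-2 clipping box (default `c(-3, 3)`), or `NULL` to
#'   skip clipping.
#' @return A smoothed [trajectory_matrix()].
#' @export
smooth_trajectories <- function(traj, order = 6, cutoff = 8,
                                bounds = c(-3, 3)) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  sm <- t(lowpass_cols(t(unclass(traj)), traj_rate(traj), cutoff, order))
  if (!is.null(bounds)) sm <- pmin(pmax(sm, bounds[1L]), bounds[2L])
  trajectory_matrix(sm, traj_rate(traj), rownames(traj))
}
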