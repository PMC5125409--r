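# Model inversion: recover articulatory (and head-motion) parameter values
# from observed sensor positions by bounded least squares, frame by frame.
#
# The face objective is linear in the parameters, so each frame is an
# exact bounded linear least-squares problem over the visible coordinates.
# Missing sensors are excluded from the objective and reconstructed
# afterwards from the fitted parameters -- the model's covariance between
# sensors is what recovers them.  The head objective is nonlinear through
# the rotations and is solved by bounded quasi-Newton from the resting
# pose.

#' Invert one face frame
#'
#' Solves `argmin || mean + loadings %*% alpha - p3d ||` over the visible
#' coordinates, subject to every component of `alpha` lying in `bounds`.
#'
#' @param p3d named coordinate vector (mm) carrying (a subset of) the
#'   model's coordinates, or a full-length unnamed vector.
#' @param model an `artmodel`.
#' @param bounds length-2 box (default `c(-3, 3)`).
#' @param visible optional logical vector over the model's coordinates;
#'   defaults to all visible (coordinates absent from a named `p3d` are
#'   treated as missing).
#' @return List with `alpha` (named parameter vector), `residual` (mm,
#'   over visible coordinates), and `reconstructed` (full coordinate
#'   vector, missing sensors included).
#' @export
invert_face_frame <- function(p3d, model, bounds = c(-3, 3),
                              visible = NULL) {
  D <- length(model$coords)
  M <- length(model$parameter_names)
  full <- rep(NA_real_, D)
  names(full) <- model$coords
  if (!is.null(names(p3d))) {
    idx <- match(names(p3d), model$coords)
    if (anyNA(idx))
      abort_artic("unknown coordinates: %s",
                  paste(names(p3d)[is.na(idx)], collapse = ", "))
    full[idx] <- p3d
  } else {
    if (length(p3d) != D)
      abort_artic("expected %d coordinates, got %d", D, length(p3d))
    full[] <- p3d
  }
  vis <- visible %||% !is.na(full)
  vis <- vis & !is.na(full)
  if (sum(vis) < M)
    abort_artic("only %d visible coordinates for %d parameters", sum(vis), M)
  fit <- bvls(model$loadings[vis, , drop = FALSE],
              full[vis] - model$mean[vis],
              lower = bounds[1L], upper = bounds[2L])
  alpha <- stats::setNames(fit$x, model$parameter_names)
  list(alpha = alpha, residual = fit$residual,
       reconstructed = predict.artmodel(model, alpha))
}

#' Invert one headset frame against a head-motion model
#'
#' Finds the bounded motion scores whose posed headset best matches the
#' observed sensor positions:
#' `argmin || RigidMotion(headset_shape, mean_motion + loadings %*% alpha) - p3d ||`
#' with every score in `bounds`.  The forward map is nonlinear through the
#' rotations; a bounded quasi-Newton search is started from the resting
#' pose `alpha = 0`.
#'
#' @param p3d `(sensors, 3)` observed headset positions in mm.
#' @param head_model a [fit_head_motion_model()] with `headset_shape` set.
#' @param bounds length-2 box (default `c(-3, 3)`).
#' @param visible optional logical vector over headset sensors.
#' @return List with `alpha` (motion scores), `motion` (the 6-vector
#'   pose), and `residual` (mm).
#' @export
invert_head_frame <- function(p3d, head_model, bounds = c(-3, 3),
                              visible = NULL) {
  shape <- head_model$headset_shape
  if (is.null(shape))
    abort_artic("head model carries no headset shape; refit with one")
  p3d <- as.matrix(p3d)
  vis <- visible %||% rep(TRUE, nrow(p3d))
  if (sum(vis) < 3L)
    abort_artic("need >= 3 visible headset sensors, got %d", sum(vis))
  if (nrow(p3d) != nrow(shape))
    abort_artic("expected %d headset sensor positions, got %d",
                nrow(shape), nrow(p3d))
  N <- ncol(head_model$loadings)
  obs <- p3d[vis, , drop = FALSE]
  ref <- shape[vis, , drop = FALSE]
  objective <- function(a) {
    mvt <- head_model$mean_motion + as.vector(head_model$loadings %*% a)
    posed <- apply_rigid_pose(ref, mvt, head_model$center)
    sum((posed - obs)^2)
  }
  resid_vec <- function(a) {
    mvt <- head_model$mean_motion + as.vector(head_model$loadings %*% a)
    as.vector(apply_rigid_pose(ref, mvt, head_model$center) - obs)
  }
  fit <- stats::optim(numeric(N), objective, method = "L-BFGS-B",
                      lower = rep(bounds[1L], N),
                      upper = rep(bounds[2L], N),
                      control = list(factr = 10, pgtol = 1e-15,
                                     maxit = 500L, ndeps = rep(1e-7, N)))
  if (fit$convergence != 0 && fit$convergence != 52)
    abort_artic("head inversion did not converge (code %d, residual %.3g mm)",
                fit$convergence, sqrt(fit$value))
  # Gauss-Newton polish: linearize the rigid forward map and take bounded
  # least-squares steps (quadratic convergence near the optimum)
  a <- fit$par
  h <- 1e-6
  for (it in seq_len(20L)) {
    r0 <- resid_vec(a)
    J <- vapply(seq_len(N), function(j) {
      e <- numeric(N); e[j] <- h
      (resid_vec(a + e) - resid_vec(a - e)) / (2 * h)
    }, numeric(length(r0)))
    step <- bvls(J, -r0, lower = bounds[1L] - a, upper = bounds[2L] - a)$x
    if (sum((resid_vec(a + step))^2) <= sum(r0^2)) a <- a + step
    else break
    if (max(abs(step)) < 1e-11) break
  }
  motion <- head_model$mean_motion + as.vector(head_model$loadings %*% a)
  list(alpha = a, motion = motion,
       residual = sqrt(sum(resid_vec(a)^2)))
}

#' Invert a whole recording into parameter trajectories
#'
#' Each frame is inverted independently by [invert_face_frame()] (frames
#' with too few visible coordinates are flagged and interpolated from
#' their neighbours), the trajectories are smoothed by the zero-phase
#' Butterworth filter, and the recording is reconstructed from the
#' smoothed parameters -- which also fills in missing sensors.
#'
#' @param series a synchronized, head-corrected [sensor_series()] carrying
#'   the model's sensors (extra sensors are ignored).
#' @param model an `artmodel`.
#' @param bounds inversion box (default `c(-3, 3)`).
#' @param smooth logical: apply [smooth_trajectories()] (default `TRUE`;
#'   automatically skipped with a warning for recordings shorter than the
#'   filter needs).
#' @param cutoff,order smoothing filter parameters (8 Hz, 6th order).
#' @return An object of class `inversion_result`: `trajectories`
#'   (smoothed [trajectory_matrix()]), `raw_trajectories`, `reconstructed`
#'   ([sensor_series()]), `per_frame_residual` (mean mm per frame over
#'   visible sensors), `residual_mean`, `residual_sd` (over all visible
#'   sensor-frames), and `flagged`.
#' @export
invert_recording <- function(series, model, bounds = c(-3, 3),
                             smooth = TRUE, cutoff = 8, order = 6) {
  sensors <- unique(sub("\\.[xyz]$", "", model$coords))
  sub <- select_sensors(series, sensors)
  mat <- series_matrix(sub)
  if (!identical(colnames(mat), model$coords))
    abort_artic("series coordinates do not match the model's")
  n <- nrow(mat)
  M <- length(model$parameter_names)
  A <- matrix(NA_real_, M, n)
  flagged <- logical(n)
  vis_all <- sub$mask[, rep(seq_along(sensors), each = 3L), drop = FALSE]
  if (n == 0L) {
    empty <- trajectory_matrix(A, sub$rate %||% 60, model$parameter_names)
    return(structure(list(trajectories = empty, raw_trajectories = empty,
                          reconstructed = sub,
                          per_frame_residual = numeric(0),
                          residual_mean = NA_real_, residual_sd = NA_real_,
                          flagged = logical(0)),
                     class = "inversion_result"))
  }
  for (i in seq_len(n)) {
    vis <- vis_all[i, ]
    if (sum(vis) < M) { flagged[i] <- TRUE; next }
    fit <- bvls(model$loadings[vis, , drop = FALSE],
                mat[i, vis] - model$mean[vis],
                lower = bounds[1L], upper = bounds[2L])
    A[, i] <- fit$x
  }
  if (all(flagged))
    abort_artic("every frame lacks enough visible coordinates to invert")
  if (any(flagged)) {
    ok <- which(!flagged)
    for (j in seq_len(M))
      A[j, flagged] <- stats::approx(ok, A[j, ok], xout = which(flagged),
                                     rule = 2)$y
  }
  raw <- trajectory_matrix(A, sub$rate, model$parameter_names)
  traj <- raw
  if (smooth) {
    if (n >= min_filter_length(order)) {
      traj <- smooth_trajectories(raw, order = order, cutoff = cutoff,
                                  bounds = bounds)
    } else {
      warning(sprintf("recording too short to smooth (%d frames); returning raw trajectories",
                      n), call. = FALSE)
    }
  }
  recon_mat <- t(predict.artmodel(model, unclass(traj)))
  colnames(recon_mat) <- model$coords
  recon <- matrix_to_series(recon_mat, sub$rate, sensors,
                            times = sub$times)
  # residuals: Euclidean distance per visible sensor per frame
  dist_frame <- matrix(NA_real_, n, length(sensors))
  for (s in seq_along(sensors)) {
    d2 <- rowSums((mat[, 3L * s - 2:0, drop = FALSE] -
                     recon_mat[, 3L * s - 2:0, drop = FALSE])^2)
    dist_frame[, s] <- ifelse(sub$mask[, s], sqrt(d2), NA_real_)
  }
  per_frame <- rowMeans(dist_frame, na.rm = TRUE)
  all_d <- dist_frame[!is.na(dist_frame)]
  structure(list(trajectories = traj, raw_trajectories = raw,
                 reconstructed = recon, per_frame_residual = per_frame,
                 residual_mean = mean(all_d), residual_sd = stats::sd(all_d),
                 flagged = flagged),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  n <- ncol(x$trajectories)
  cat(sprintf("Inversion result: %d frames, %d parameters\n",
              n, nrow(x$trajectories)))
  if (n > 0L)
    cat(sprintf("  reconstruction error: M = %.3f mm, SD = %.3f mm\n",
                x$residual_mean, x$residual_sd))
  if (any(x$flagged))
    cat(sprintf("  %d frames interpolated (too few visible coordinates)\n",
                sum(x$flagged)))
  invisible(x)
}

#' @export
summary.inversion_result <- function(object, ...) {
  data.frame(frames = ncol(object$trajectories),
             parameters = nrow(object$trajectories),
             residual_mean_mm = object$residual_mean,
             residual_sd_mm = object$residual_sd,
             flagged_frames = sum(object$flagged))
}

#' Residuals of an inversion
#' @param object an `inversion_result`.
#' @param ... unused.
#' @return Per-frame mean reconstruction error in mm.
#' @export
residuals.inversion_result <- function(object, ...) {
  object$per_frame_residual
}
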