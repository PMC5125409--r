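# Rigid head-motion estimation and removal.
#
# Head pose per frame is a rotation about a single centre of rotation (the
# neck point, estimated jointly with the motion) plus a translation:
#   x_world = R (x_head - c) + c + T
# Rotations are parameterized as intrinsic z-y-x Euler angles in degrees.
# The per-frame fit is the unweighted least-squares rigid alignment
# (orthogonal Procrustes / Kabsch) of the rigid sensors onto a reference.

#' Rotation matrix from Euler angles
#'
#' Intrinsic z-y-x convention: `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`.
#' @param rx,ry,rz angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_rotation <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; g <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_rotation()]; angles returned in degrees, in
#' `(-180, 180]`.
#' @param R a 3x3 rotation matrix.
#' @return Numeric vector `c(rx, ry, rz)` in degrees.
#' @export
rotation_to_euler <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-10) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: fold the indeterminate angle into rz
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  }
  deg <- c(rx, ry, rz) * 180 / pi
  deg[deg <= -180] <- deg[deg <= -180] + 360
  deg
}

#' Create a rigid motion series
#'
#' @param params numeric matrix `(frames, 6)` with columns
#'   `Tx, Ty, Tz` (mm) and `Rx, Ry, Rz` (degrees).
#' @param times frame times in seconds.
#' @param center 3-D centre of rotation (mm), one point for the whole
#'   recording.
#' @param flagged optional logical vector marking frames whose pose was
#'   interpolated rather than estimated.
#' @return An object of class `rigid_motion`.
#' @export
rigid_motion <- function(params, times, center, flagged = NULL) {
  params <- as.matrix(params)
  if (ncol(params) != 6L)
    abort_artic("'params' must have 6 columns (Tx, Ty, Tz, Rx, Ry, Rz)")
  if (nrow(params) != length(times))
    abort_artic("need one time per frame")
  rot <- params[, 4:6, drop = FALSE]
  rot <- ((rot + 180) %% 360) - 180
  rot[rot == -180] <- 180
  params[, 4:6] <- rot
  colnames(params) <- c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz")
  structure(list(params = params, times = as.numeric(times),
                 center = as.numeric(center),
                 flagged = flagged %||% rep(FALSE, nrow(params))),
            class = "rigid_motion")
}

#' @export
print.rigid_motion <- function(x, ...) {
  cat(sprintf("Rigid motion series: %d frames, centre (%.2f, %.2f, %.2f) mm\n",
              nrow(x$params), x$center[1L], x$center[2L], x$center[3L]))
  cat(sprintf("  translation RMS: %.3f mm, rotation RMS: %.3f deg\n",
              sqrt(mean(x$params[, 1:3]^2)), sqrt(mean(x$params[, 4:6]^2))))
  if (any(x$flagged))
    cat(sprintf("  %d frames interpolated (too few rigid sensors)\n",
                sum(x$flagged)))
  invisible(x)
}

#' Apply one rigid pose to a set of points
#'
#' @param points `(n, 3)` matrix of head-frame points in mm.
#' @param sixvec numeric vector `c(Tx, Ty, Tz, Rx, Ry, Rz)`.
#' @param center centre of rotation (mm).
#' @return The transformed `(n, 3)` matrix.
#' @export
apply_rigid_pose <- function(points, sixvec, center) {
  R <- euler_to_rotation(sixvec[4L], sixvec[5L], sixvec[6L])
  centered <- sweep(as.matrix(points), 2L, center)
  sweep(centered %*% t(R), 2L, center + sixvec[1:3], `+`)
}

#' Per-frame rotation matrix entries, vectorized over frames
#' @noRd
rotation_entries <- function(params) {
  a <- params[, 4L] * pi / 180
  b <- params[, 5L] * pi / 180
  g <- params[, 6L] * pi / 180
  sx <- sin(a); cx <- cos(a); sy <- sin(b); cy <- cos(b)
  sz <- sin(g); cz <- cos(g)
  list(R11 = cz * cy, R12 = cz * sy * sx - sz * cx,
       R13 = cz * sy * cx + sz * sx,
       R21 = sz * cy, R22 = sz * sy * sx + cz * cx,
       R23 = sz * sy * cx - cz * sx,
       R31 = -sy, R32 = cy * sx, R33 = cy * cx)
}

#' Apply per-frame rigid poses to a (frames x sensors x 3) array
#' @noRd
rigid_pose_batch <- function(pos, params, center, inverse = FALSE) {
  E <- rotation_entries(params)
  out <- pos
  S <- dim(pos)[2L]
  for (s in seq_len(S)) {
    if (!inverse) {
      x <- pos[, s, 1L] - center[1L]
      y <- pos[, s, 2L] - center[2L]
      z <- pos[, s, 3L] - center[3L]
      out[, s, 1L] <- E$R11 * x + E$R12 * y + E$R13 * z +
        center[1L] + params[, 1L]
      out[, s, 2L] <- E$R21 * x + E$R22 * y + E$R23 * z +
        center[2L] + params[, 2L]
      out[, s, 3L] <- E$R31 * x + E$R32 * y + E$R33 * z +
        center[3L] + params[, 3L]
    } else {
      x <- pos[, s, 1L] - center[1L] - params[, 1L]
      y <- pos[, s, 2L] - center[2L] - params[, 2L]
      z <- pos[, s, 3L] - center[3L] - params[, 3L]
      out[, s, 1L] <- E$R11 * x + E$R21 * y + E$R31 * z + center[1L]
      out[, s, 2L] <- E$R12 * x + E$R22 * y + E$R32 * z + center[2L]
      out[, s, 3L] <- E$R13 * x + E$R23 * y + E$R33 * z + center[3L]
    }
  }
  out
}

#' Least-squares rigid alignment of one point set onto another (Kabsch)
#' @noRd
kabsch <- function(from, to) {
  mf <- colMeans(from); mt <- colMeans(to)
  H <- crossprod(sweep(from, 2L, mf), sweep(to, 2L, mt))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = mt - as.vector(R %*% mf),
       rank = sum(svd(sweep(from, 2L, mf))$d > 1e-8))
}

#' Estimate rigid head motion from rigid sensors
#'
#' For every frame the rotation and translation mapping the reference
#' configuration of the rigid sensors (headset, nasion, tragus) onto the
#' observed one is found by unweighted orthogonal Procrustes.  A single
#' centre of rotation -- the point minimizing the residual translation
#' magnitude across all frames -- is then estimated jointly, and the
#' per-frame translations are re-expressed about it.  Frames with fewer
#' than 3 visible, non-collinear rigid sensors are flagged and their pose
#' linearly interpolated from neighbouring frames.
#'
#' @param series a [sensor_series()] containing the rigid sensors.
#' @param rigid_sensors names of the sensors rigid with the skull.
#' @param reference_frame frame index defining the head frame (default 1),
#'   or a `(sensors, 3)` matrix of reference positions.
#' @param center optional known centre of rotation; when `NULL` (default)
#'   it is estimated jointly with the motion.
#' @return A [rigid_motion()] series.
#' @export
estimate_rigid_motion <- function(series, rigid_sensors,
                                  reference_frame = 1L, center = NULL) {
  rig <- select_sensors(series, rigid_sensors)
  n <- n_frames(rig)
  if (is.matrix(reference_frame)) {
    ref <- reference_frame
    if (!identical(dim(ref), c(length(rigid_sensors), 3L)))
      abort_artic("reference matrix must be (%d x 3)", length(rigid_sensors))
  } else {
    if (!all(rig$mask[reference_frame, ]))
      abort_artic("reference frame %d has missing rigid sensors",
                  reference_frame)
    ref <- rig$positions[reference_frame, , ]
  }
  Rs <- vector("list", n)
  ts <- matrix(NA_real_, n, 3L)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    vis <- rig$mask[i, ]
    if (sum(vis) < 3L) { flagged[i] <- TRUE; next }
    fit <- kabsch(ref[vis, , drop = FALSE],
                  rig$positions[i, vis, , drop = FALSE][1, , ])
    if (fit$rank < 2L) { flagged[i] <- TRUE; next }
    Rs[[i]] <- fit$R
    ts[i, ] <- fit$t
  }
  if (all(flagged))
    abort_artic("no frame has >= 3 visible, non-collinear rigid sensors")
  ok <- which(!flagged)
  if (is.null(center)) {
    # centre of rotation: c minimizing sum_t || t_t - (I - R_t) c ||^2
    A <- matrix(0, 3L, 3L); b <- numeric(3L)
    for (i in ok) {
      M <- diag(3L) - Rs[[i]]
      A <- A + crossprod(M)
      b <- b + as.vector(crossprod(M, ts[i, ]))
    }
    # tiny ridge keeps c identifiable when rotations are (near) zero
    center <- solve(A + diag(1e-9, 3L), b)
  }
  params <- matrix(NA_real_, n, 6L)
  for (i in ok) {
    params[i, 4:6] <- rotation_to_euler(Rs[[i]])
    params[i, 1:3] <- ts[i, ] - as.vector((diag(3L) - Rs[[i]]) %*% center)
  }
  if (any(flagged)) {
    idx <- seq_len(n)
    for (j in seq_len(6L))
      params[flagged, j] <- stats::approx(idx[ok], params[ok, j],
                                          xout = idx[flagged], rule = 2)$y
  }
  rigid_motion(params, series$times, center, flagged = flagged)
}

#' Apply a rigid motion series to a sensor series
#'
#' Poses every frame of a head-frame series by the corresponding rigid
#' transform.  Inverse of [remove_rigid_motion()].
#'
#' @param series a head-frame [sensor_series()].
#' @param rigid a [rigid_motion()] with matching times.
#' @return The posed [sensor_series()].
#' @export
apply_rigid_motion <- function(series, rigid) {
  check_rigid_times(series, rigid)
  pos <- rigid_pose_batch(series$positions, rigid$params, rigid$center)
  sensor_series(pos, series$rate, series$sensor_names, times = series$times,
                mask = series$mask)
}

#' Remove rigid head motion from a sensor series
#'
#' Expresses every frame in the head frame:
#' `x_head = R^T (x_world - c - T) + c`.  Applying
#' [estimate_rigid_motion()] to the output yields the identity motion, and
#' within-frame distances between sensors are preserved.
#'
#' @inheritParams apply_rigid_motion
#' @return The head-frame [sensor_series()].
#' @export
remove_rigid_motion <- function(series, rigid) {
  check_rigid_times(series, rigid)
  pos <- rigid_pose_batch(series$positions, rigid$params, rigid$center,
                          inverse = TRUE)
  sensor_series(pos, series$rate, series$sensor_names, times = series$times,
                mask = series$mask)
}

check_rigid_times <- function(series, rigid) {
  if (n_frames(series) != nrow(rigid$params) ||
      max(abs(series$times - rigid$times)) > 1e-9)
    abort_artic("series and rigid motion times do not match")
  invisible(TRUE)
}

#' Fit a PCA model of rigid head motion
#'
#' PCA of the 6-dimensional rigid pose vectors (Tx, Ty, Tz, Rx, Ry, Rz).
#' Loadings are scaled so that scores are in standard-deviation units, which
#' makes the `[-3, 3]` inversion box mean the same thing for every
#' component.  Components with (numerically) zero variance are dropped with
#' a warning.
#'
#' @param rigid a [rigid_motion()] series with at least 7 frames.
#' @param headset_shape `(sensors, 3)` mean head-frame positions of the
#'   headset sensors, carried along for headset-based inversion; optional.
#' @param headset_sensors names matching `headset_shape` rows; optional.
#' @return An object of class `head_motion_model` with fields
#'   `mean_motion` (6-vector), `loadings` (6 x N, per score-SD),
#'   `score_sd`, `explained` (% of variance per component), `center`,
#'   `headset_shape`, `headset_sensors`.
#' @export
fit_head_motion_model <- function(rigid, headset_shape = NULL,
                                  headset_sensors = NULL) {
  X <- rigid$params
  if (nrow(X) < 7L)
    abort_artic("need >= 7 frames to fit a 6-dimensional motion model")
  mu <- colMeans(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  sd <- pc$sdev
  keep <- which(sd > 1e-10 * max(sd, 1e-300))
  if (length(keep) == 0L)
    abort_artic("rigid motion has zero variance; nothing to model")
  if (length(keep) < 6L)
    warning(sprintf("rigid motion is rank-deficient: keeping %d of 6 components",
                    length(keep)), call. = FALSE)
  loadings <- pc$rotation[, keep, drop = FALSE] %*%
    diag(sd[keep], length(keep))
  expl <- 100 * sd[keep]^2 / sum(sd^2)
  structure(list(mean_motion = mu, loadings = loadings,
                 score_sd = sd[keep], explained = expl,
                 center = rigid$center,
                 headset_shape = headset_shape,
                 headset_sensors = headset_sensors),
            class = "head_motion_model")
}

#' @export
print.head_motion_model <- function(x, ...) {
  cat(sprintf("Head motion model: %d components\n", ncol(x$loadings)))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", x$explained), collapse = ", "), "\n")
  invisible(x)
}
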