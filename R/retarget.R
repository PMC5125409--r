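# Avatar retargeting: convert face key frames into synthetic articulatory
# parameters, fit tongue key-frame mixtures against EMA postures, and
# build the avatar's own 5-parameter tongue model.

#' Create a key-frame set
#'
#' @param neutral `(vertices, 3)` matrix of the neutral mesh pose.
#' @param keyframes named list of `(vertices, 3)` matrices, one per key
#'   frame, sharing the neutral's vertex count.
#' @param correspondence named integer vector mapping EMA sensor names
#'   (e.g. `TT`, `TB`, `TD`) to mesh vertex indices.
#' @return An object of class `keyframe_set`.
#' @export
keyframe_set <- function(neutral, keyframes, correspondence = NULL) {
  neutral <- as.matrix(neutral)
  if (ncol(neutral) != 3L) abort_artic("'neutral' must be (vertices x 3)")
  if (length(keyframes) == 0L || is.null(names(keyframes)))
    abort_artic("'keyframes' must be a non-empty named list")
  for (nm in names(keyframes)) {
    k <- as.matrix(keyframes[[nm]])
    if (!identical(dim(k), dim(neutral)))
      abort_artic("key frame '%s' does not share the neutral's topology", nm)
    keyframes[[nm]] <- k
  }
  if (!is.null(correspondence)) {
    if (is.null(names(correspondence)))
      abort_artic("'correspondence' must be named by sensor")
    if (any(correspondence < 1L) || any(correspondence > nrow(neutral)))
      abort_artic("correspondence indices out of range 1..%d", nrow(neutral))
  }
  structure(list(neutral = neutral, keyframes = keyframes,
                 correspondence = correspondence),
            class = "keyframe_set")
}

#' @export
print.keyframe_set <- function(x, ...) {
  cat(sprintf("Key-frame set: %d key frames, %d vertices\n",
              length(x$keyframes), nrow(x$neutral)))
  cat("  key frames:", paste(names(x$keyframes), collapse = ", "), "\n")
  if (!is.null(x$correspondence))
    cat("  sensor correspondence:",
        paste(names(x$correspondence), x$correspondence, sep = "->",
              collapse = ", "), "\n")
  invisible(x)
}

#' Convert face key frames into synthetic articulatory parameters
#'
#' Each key frame's displacement from the neutral pose is
#' variance-normalized (scaled so the root-mean-square per-vertex
#' displacement is 1) and treated as a one-sided articulatory parameter
#' whose activation varies in `[0, +3]`: key frames are extreme poses, and
#' a mesh has no physical "negative" pose beyond neutral.
#'
#' @param keyframes a [keyframe_set()] whose key frames are named after
#'   the articulatory parameters they realize (e.g. `jaw1`, `lips1`,
#'   `lips2`, `lips3`).
#' @return An object of class `avatar_face_params`: `neutral`, `loadings`
#'   (`3 * vertices` x key frames, displacement per activation unit),
#'   `parameter_names`, `activation_range = c(0, 3)`.
#' @export
face_keyframes_to_params <- function(keyframes) {
  stopifnot(inherits(keyframes, "keyframe_set"))
  V <- nrow(keyframes$neutral)
  nk <- length(keyframes$keyframes)
  loadings <- matrix(0, 3L * V, nk)
  for (i in seq_len(nk)) {
    nm <- names(keyframes$keyframes)[i]
    disp <- keyframes$keyframes[[i]] - keyframes$neutral
    s <- sqrt(mean(rowSums(disp^2)))
    if (s < 1e-12)
      abort_artic("key frame '%s' is identical to the neutral pose", nm)
    loadings[, i] <- as.vector(t(disp)) / s
  }
  structure(list(neutral = keyframes$neutral, loadings = loadings,
                 parameter_names = names(keyframes$keyframes),
                 activation_range = c(0, 3)),
            class = "avatar_face_params")
}

#' Pose the avatar face from parameter activations
#'
#' @param params an `avatar_face_params` object.
#' @param activations named or positional numeric vector in the activation
#'   range (one value per parameter).
#' @return `(vertices, 3)` posed mesh.
#' @export
avatar_face_pose <- function(params, activations) {
  nk <- length(params$parameter_names)
  if (!is.null(names(activations)))
    activations <- activations[params$parameter_names]
  if (length(activations) != nk)
    abort_artic("expected %d activations", nk)
  flat <- as.vector(t(params$neutral)) +
    as.vector(params$loadings %*% as.numeric(activations))
  matrix(flat, ncol = 3L, byrow = TRUE)
}

#' Fit a bounded key-frame mixture to one EMA tongue posture
#'
#' Solves `argmin || sum_i alpha_i K_i - p3d_ema ||` on the mesh vertices
#' corresponding to the EMA sensors, with each weight in `bounds`
#' (default `[-10, 10]`).  The fitted full mesh is the same mixture
#' evaluated on all vertices.
#'
#' @param ema_pos `(sensors, 3)` matrix of EMA positions (mm), rows named
#'   (or ordered) as in the key-frame set's correspondence.
#' @param keyframes a [keyframe_set()] with `correspondence` set.
#' @param bounds weight box (default `c(-10, 10)`).
#' @return List with `weights` (named by key frame), `mesh`
#'   (`(vertices, 3)` fitted tongue mesh), `residual_per_sensor` (mm) and
#'   `residual` (total mm).
#' @export
fit_tongue_mixture <- function(ema_pos, keyframes, bounds = c(-10, 10)) {
  stopifnot(inherits(keyframes, "keyframe_set"))
  corr <- keyframes$correspondence
  if (is.null(corr))
    abort_artic("key-frame set has no sensor-to-vertex correspondence")
  ema_pos <- as.matrix(ema_pos)
  if (!is.null(rownames(ema_pos))) ema_pos <- ema_pos[names(corr), , drop = FALSE]
  if (nrow(ema_pos) != length(corr))
    abort_artic("expected %d sensor positions", length(corr))
  N <- length(keyframes$keyframes)
  A <- vapply(keyframes$keyframes,
              function(k) as.vector(t(k[corr, , drop = FALSE])),
              numeric(3L * length(corr)))
  b <- as.vector(t(ema_pos))
  ridge <- 1e-12
  if (qr(A)$rank < min(dim(A))) {
    warning("rank-deficient key-frame matrix; using ridge 1e-8 for a minimal-norm solution",
            call. = FALSE)
    ridge <- 1e-8
  }
  fit <- bvls(A, b, lower = bounds[1L], upper = bounds[2L], ridge = ridge)
  w <- stats::setNames(fit$x, names(keyframes$keyframes))
  mesh <- Reduce(`+`, Map(function(k, wi) k * wi, keyframes$keyframes, w))
  fitted_sensors <- mesh[corr, , drop = FALSE]
  per_sensor <- sqrt(rowSums((fitted_sensors - ema_pos)^2))
  names(per_sensor) <- names(corr)
  list(weights = w, mesh = mesh, residual_per_sensor = per_sensor,
       residual = fit$residual)
}

#' Fit tongue meshes to every posture of a quantized EMA database
#'
#' @param quantized_ema a [prune_frames()] result whose coordinates
#'   include the tongue sensors named in the correspondence.
#' @param keyframes a [keyframe_set()] with `correspondence`.
#' @param bounds weight box (default `c(-10, 10)`).
#' @return An object of class `tongue_posture_db`: `meshes`
#'   (`(postures, 3 * vertices)`), `weights` (`(postures, keyframes)`),
#'   `residuals` (`(postures, sensors)` mm), `summary` (mean/SD residual),
#'   and the coordinate names of the EMA postures.
#' @export
build_tongue_posture_db <- function(quantized_ema, keyframes,
                                    bounds = c(-10, 10)) {
  stopifnot(inherits(keyframes, "keyframe_set"))
  corr <- keyframes$correspondence
  coords <- colnames(quantized_ema$coords)
  need <- coord_names(names(corr))
  if (!all(need %in% coords))
    abort_artic("quantized database lacks coordinates: %s",
                paste(setdiff(need, coords), collapse = ", "))
  n <- nrow(quantized_ema$coords)
  V <- nrow(keyframes$neutral)
  meshes <- matrix(0, n, 3L * V)
  weights <- matrix(0, n, length(keyframes$keyframes))
  res <- matrix(0, n, length(corr))
  for (i in seq_len(n)) {
    ema <- matrix(quantized_ema$coords[i, need], ncol = 3L, byrow = TRUE)
    rownames(ema) <- names(corr)
    fit <- fit_tongue_mixture(ema, keyframes, bounds = bounds)
    meshes[i, ] <- as.vector(t(fit$mesh))
    weights[i, ] <- fit$weights
    res[i, ] <- fit$residual_per_sensor
  }
  colnames(weights) <- names(keyframes$keyframes)
  colnames(res) <- names(corr)
  colnames(meshes) <- coord_names(paste0("vtx_", seq_len(V)))
  structure(list(meshes = meshes, weights = weights, residuals = res,
                 summary = c(mean = if (n) mean(res) else NA_real_,
                             sd = if (n > 1L) stats::sd(as.vector(res))
                                  else NA_real_),
                 ema_coords = need),
            class = "tongue_posture_db")
}

#' @export
print.tongue_posture_db <- function(x, ...) {
  cat(sprintf("Tongue posture database: %d postures, %d mesh coordinates\n",
              nrow(x$meshes), ncol(x$meshes)))
  if (nrow(x$meshes))
    cat(sprintf("  sensor-fit residual: M = %.3f mm, SD = %.3f mm\n",
                x$summary[["mean"]], x$summary[["sd"]]))
  invisible(x)
}

#' Default 5-parameter avatar tongue extraction scheme
#'
#' @param jaw jaw sensor names driving `jaw1` (must be present in the
#'   frame matrix handed to the fit).
#' @param tongue_body,tongue_tip tongue sensor names.
#' @return An [extraction_scheme()] with `jaw1, tongue1..tongue4`.
#' @export
avatar_tongue_scheme <- function(jaw = paste0("jaw_", 1:3),
                                 tongue_body = c("TB", "TD"),
                                 tongue_tip = "TT") {
  extraction_scheme(list(jaw1 = jaw, tongue1 = tongue_body,
                         tongue2 = tongue_body, tongue3 = tongue_tip,
                         tongue4 = tongue_tip))
}

#' Fit the avatar's articulatory tongue model
#'
#' Runs the guided-PCA procedure on the concatenation of the fitted tongue
#' mesh coordinates and the quantized sensor coordinates, with a 5-step
#' scheme (`jaw1`, `tongue1..tongue4`).  The extracted parameters are
#' anchored on the sensor landmarks but their loadings extend over all
#' mesh vertices, so speaker trajectories drive the full avatar tongue.
#'
#' @param posture_db a [build_tongue_posture_db()] result.
#' @param quantized a [prune_frames()] result aligned row-for-row with the
#'   posture database (the same database the postures were fitted to).
#' @param scheme extraction scheme (default [avatar_tongue_scheme()]).
#' @return An `artmodel` over mesh + sensor coordinates.
#' @export
fit_avatar_tongue_model <- function(posture_db, quantized,
                                    scheme = avatar_tongue_scheme()) {
  stopifnot(inherits(posture_db, "tongue_posture_db"))
  if (nrow(posture_db$meshes) != nrow(quantized$coords))
    abort_artic("posture database and quantized frames are not aligned (%d vs %d rows)",
                nrow(posture_db$meshes), nrow(quantized$coords))
  frames <- cbind(posture_db$meshes, quantized$coords)
  fit_guided_pca(frames, scheme = scheme)
}

#' Align avatar parameter signs with the speaker's model
#'
#' The avatar and speaker parameters share topology (both `jaw1` open the
#' jaw) but a positive score may move them in opposite directions; the
#' sign table, determined by inspection, flips the avatar loadings so
#' speaker trajectories drive the avatar correctly.  Applying a table
#' twice is the identity.
#'
#' @param speaker_model the speaker's `artmodel` (names are validated
#'   against it).
#' @param avatar_model the avatar's `artmodel`.
#' @param sign_table named numeric vector of `+1`/`-1` per parameter;
#'   parameters not listed keep their sign.
#' @return The avatar `artmodel` with flipped loadings.
#' @export
align_parameter_signs <- function(speaker_model, avatar_model, sign_table) {
  if (is.null(names(sign_table)))
    abort_artic("'sign_table' must be named by parameter")
  unknown <- setdiff(names(sign_table),
                     intersect(speaker_model$parameter_names,
                               avatar_model$parameter_names))
  if (length(unknown))
    abort_artic("unknown parameter(s) in sign table: %s",
                paste(unknown, collapse = ", "))
  if (!all(sign_table %in% c(-1, 1)))
    abort_artic("signs must be +1 or -1")
  out <- avatar_model
  for (nm in names(sign_table))
    out$loadings[, nm] <- sign_table[[nm]] * out$loadings[, nm]
  out
}
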