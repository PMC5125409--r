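# Guided principal component analysis of articulatory data.
#
# Each articulatory parameter is extracted from a designated landmark
# subset: the first principal direction of the current residual restricted
# to the subset gives the parameter's score; the score is standardized to
# unit variance; the whole-face loading is the regression of every residual
# coordinate on the standardized score; and the rank-one contribution is
# subtracted before the next step.  Iterating over articulators (jaw first,
# because the tongue and lips ride on the jaw) yields parameters with a
# phonetic interpretation, unlike plain PCA whose components mix
# articulators.

#' Define a guided-PCA extraction scheme
#'
#' @param steps named list: parameter name -> character vector of landmark
#'   coordinates.  Entries may be sensor names (`"TT"`, expanded to
#'   `TT.x, TT.y, TT.z`) or individual coordinates (`"TT.y"`).
#' @param signs optional named numeric vector of `+1`/`-1` per parameter;
#'   flips the fitted loading after the default sign normalization.
#' @return An object of class `extraction_scheme`.
#' @examples
#' extraction_scheme(list(jaw1 = c("jaw_1", "jaw_2"), tongue1 = c("TB", "TD")))
#' @export
extraction_scheme <- function(steps, signs = NULL) {
  if (length(steps) == 0L || is.null(names(steps)) ||
      any(!nzchar(names(steps))))
    abort_artic("'steps' must be a non-empty named list")
  if (anyDuplicated(names(steps)))
    abort_artic("parameter names must be unique")
  if (any(vapply(steps, length, 1L) == 0L))
    abort_artic("every step needs a non-empty landmark subset")
  signs <- signs %||% stats::setNames(rep(1, length(steps)), names(steps))
  if (!all(names(steps) %in% names(signs)))
    signs <- stats::setNames(ifelse(names(steps) %in% names(signs),
                                    signs[names(steps)], 1), names(steps))
  if (!all(signs %in% c(-1, 1)))
    abort_artic("signs must be +1 or -1")
  structure(list(steps = steps, signs = signs[names(steps)]),
            class = "extraction_scheme")
}

#' @export
print.extraction_scheme <- function(x, ...) {
  cat(sprintf("Extraction scheme: %d parameters\n", length(x$steps)))
  for (nm in names(x$steps))
    cat(sprintf("  %-10s <- %s\n", nm, paste(x$steps[[nm]], collapse = ", ")))
  invisible(x)
}

#' The default 10-parameter face-and-tongue extraction scheme
#'
#' Extraction order follows the articulatory hierarchy: jaw opening first
#' (the tongue is carried by the jaw), then tongue body (front-back,
#' flattening-bunching on TB and TD), tongue tip (vertical then horizontal
#' on TT), lips (rounding on all lip sensors, closing on the lower lip,
#' raising on the upper lip), residual jaw rotation, and eyebrows.
#'
#' @param jaw,lower_lip,upper_lip,eyebrows sensor name vectors for each
#'   articulator group.
#' @param tongue_body,tongue_tip tongue sensor names (defaults `TB`,`TD`
#'   and `TT`).
#' @return An [extraction_scheme()] with parameters `jaw1, tongue1,
#'   tongue2, tongue3, tongue4, lips1, lips2, lips3, jaw2, eyebrows1`.
#' @export
default_extraction_scheme <- function(jaw = paste0("jaw_", 1:3),
                                      lower_lip = paste0("lipL_", 1:4),
                                      upper_lip = paste0("lipU_", 1:4),
                                      eyebrows = paste0("brow_", 1:6),
                                      tongue_body = c("TB", "TD"),
                                      tongue_tip = "TT") {
  extraction_scheme(list(
    jaw1      = jaw,
    tongue1   = tongue_body,
    tongue2   = tongue_body,
    tongue3   = tongue_tip,
    tongue4   = tongue_tip,
    lips1     = c(lower_lip, upper_lip),
    lips2     = lower_lip,
    lips3     = upper_lip,
    jaw2      = jaw,
    eyebrows1 = eyebrows))
}

#' Expand scheme subset entries to coordinate column indices
#' @noRd
scheme_columns <- function(subset, coords) {
  expand <- unlist(lapply(subset, function(s) {
    if (s %in% coords) return(s)
    cand <- paste(s, c("x", "y", "z"), sep = ".")
    hit <- cand[cand %in% coords]
    if (length(hit) == 0L)
      abort_artic("landmark '%s' matches no data coordinate", s)
    hit
  }))
  match(unique(expand), coords)
}

new_artmodel <- function(mean, loadings, parameter_names,
                         variance_fractions, total_variance, scheme,
                         coords, n_frames = NA_integer_) {
  loadings <- as.matrix(loadings)
  colnames(loadings) <- parameter_names
  rownames(loadings) <- coords
  names(mean) <- coords
  structure(list(mean = mean, loadings = loadings,
                 parameter_names = parameter_names,
                 variance_fractions = variance_fractions,
                 total_variance = total_variance,
                 scheme = scheme, coords = coords, n_frames = n_frames),
            class = "artmodel")
}

#' Fit a guided-PCA articulatory model
#'
#' @param frames a [prune_frames()] result, or a numeric
#'   `(frames, coordinates)` matrix with coordinate column names.
#' @param scheme an [extraction_scheme()]; defaults to
#'   [default_extraction_scheme()].
#' @return An object of class `artmodel` with fields `mean` (mm),
#'   `loadings` (coordinates x parameters, mm per score-SD),
#'   `parameter_names`, `variance_fractions` (% of global variance removed
#'   per step), `total_variance`, `scheme` and `coords`.  Scores are in
#'   standard-deviation units, so driving a parameter across `[-3, 3]`
#'   spans +/- 3 SD of its natural excursion.
#' @seealso [predict.artmodel()], [variance_report()], [invert_face_frame()]
#' @export
fit_guided_pca <- function(frames, scheme = default_extraction_scheme()) {
  X <- if (inherits(frames, "quantized_frames")) frames$coords
       else as.matrix(frames)
  if (is.null(colnames(X)))
    abort_artic("frame matrix must have coordinate column names")
  stopifnot(inherits(scheme, "extraction_scheme"))
  M <- length(scheme$steps)
  n <- nrow(X)
  if (n < 2L * M)
    abort_artic("need at least %d frames to extract %d parameters (got %d)",
                2L * M, M, n)
  coords <- colnames(X)
  mu <- colMeans(X)
  R <- sweep(X, 2L, mu)
  total_var <- sum(colSums(R^2)) / (n - 1L)
  if (total_var <= 0)
    abort_artic("data has zero variance")
  loadings <- matrix(0, ncol(X), M)
  fractions <- numeric(M)
  resid_var <- total_var
  scale_ref <- sqrt(total_var / ncol(X))
  for (k in seq_len(M)) {
    nm <- names(scheme$steps)[k]
    idx <- scheme_columns(scheme$steps[[k]], coords)
    sub <- R[, idx, drop = FALSE]
    sv <- svd(sub, nu = 0L, nv = 1L)
    if (sv$d[1L] / sqrt(n - 1L) < 1e-12 * scale_ref)
      abort_artic("zero residual variance on the '%s' subset (step %d)",
                  nm, k)
    u <- sv$v[, 1L]
    # deterministic sign: largest-|loading| subset coordinate positive
    u <- u * sign(u[which.max(abs(u))]) * scheme$signs[k]
    score <- as.vector(sub %*% u)
    sd_k <- sqrt(sum(score^2) / (n - 1L))
    score <- score / sd_k
    v <- as.vector(crossprod(R, score)) / (n - 1L)
    R <- R - tcrossprod(score, v)
    new_resid <- sum(colSums(R^2)) / (n - 1L)
    fractions[k] <- 100 * (resid_var - new_resid) / total_var
    resid_var <- new_resid
    loadings[, k] <- v
  }
  names(fractions) <- names(scheme$steps)
  new_artmodel(mu, loadings, names(scheme$steps), fractions, total_var,
               scheme, coords, n_frames = n)
}

#' @export
print.artmodel <- function(x, ...) {
  cat(sprintf("Guided-PCA articulatory model: %d parameters, %d coordinates\n",
              length(x$parameter_names), length(x$coords)))
  cat(sprintf("  variance captured: %.1f%% of global\n",
              sum(x$variance_fractions)))
  cat("  parameters:", paste(x$parameter_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.artmodel <- function(object, ...) {
  out <- data.frame(parameter = object$parameter_names,
                    percent_global_variance = object$variance_fractions,
                    loading_norm_mm = sqrt(colSums(object$loadings^2)),
                    row.names = NULL)
  class(out) <- c("summary.artmodel", "data.frame")
  out
}

#' @export
print.summary.artmodel <- function(x, ...) {
  cat("Articulatory model variance accounting\n")
  print.data.frame(cbind(x[1L],
                         round(x[-1L], 3L)), row.names = FALSE)
  cat(sprintf("total captured: %.2f%%\n", sum(x$percent_global_variance)))
  invisible(x)
}

#' @export
coef.artmodel <- function(object, ...) object$loadings

#' Project articulatory parameters to sensor coordinates
#'
#' Computes `mean + loadings %*% alpha`: the sensor configuration produced
#' by a vector (or trajectory) of parameter values.
#'
#' @param object an `artmodel`.
#' @param newdata numeric vector of length M, `(M, frames)` matrix, or a
#'   [trajectory_matrix()].  Defaults to the zero vector (the mean face).
#' @param ... unused.
#' @return For a vector input, a named coordinate vector (mm); for a
#'   matrix, a `(coordinates, frames)` matrix.
#' @export
predict.artmodel <- function(object, newdata = NULL, ...) {
  M <- length(object$parameter_names)
  if (is.null(newdata)) newdata <- numeric(M)
  if (is.vector(newdata)) {
    if (length(newdata) != M)
      abort_artic("expected %d parameter values, got %d", M, length(newdata))
    return(object$mean + as.vector(object$loadings %*% newdata))
  }
  a <- unclass(newdata)
  if (nrow(a) != M)
    abort_artic("expected %d parameter rows, got %d", M, nrow(a))
  object$mean + object$loadings %*% a
}

#' @rdname predict.artmodel
#' @param model an `artmodel`.
#' @param alpha parameter values as in `newdata`.
#' @export
project_frame <- function(model, alpha) predict.artmodel(model, alpha)

#' Simulate sensor frames from an articulatory model
#'
#' Draws independent standard-normal scores for every parameter and
#' projects them through the model.
#'
#' @param object an `artmodel`.
#' @param nsim number of frames.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param ... unused.
#' @return A `(nsim, coordinates)` matrix with named columns.
#' @export
simulate.artmodel <- function(object, nsim = 1, seed = NULL, ...) {
  M <- length(object$parameter_names)
  draw <- function() matrix(stats::rnorm(nsim * M), M, nsim)
  a <- if (is.null(seed)) draw() else with_seed(seed, draw())
  t(predict.artmodel(object, a))
}

#' @export
plot.artmodel <- function(x, ...) {
  graphics::barplot(x$variance_fractions, las = 2,
                    ylab = "% of global variance",
                    main = "Guided-PCA variance accounting", ...)
  invisible(x)
}

#' Recompute the per-parameter variance accounting on given frames
#'
#' Re-runs the model's extraction scheme on `frames` and reports the
#' percentage of global variance removed at each step.  On the fitting data
#' this reproduces the stored fractions; on fresh data from the same
#' population it estimates them.
#'
#' @param model an `artmodel`.
#' @param frames a [prune_frames()] result or coordinate matrix (must carry
#'   the model's coordinates).
#' @return Data frame with columns `parameter` and `percent`.
#' @export
variance_report <- function(model, frames) {
  refit <- fit_guided_pca(frames, scheme = model$scheme)
  data.frame(parameter = refit$parameter_names,
             percent = unname(refit$variance_fractions))
}
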