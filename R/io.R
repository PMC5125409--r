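# On-disk model, dictionary and sensor-series formats.
#
# Models and dictionaries are stored as self-describing JSON containers
# with a schema tag (`format`, `version`) and full-precision float64
# arrays; loading a saved object reproduces it to numeric round-off.

model_format_tag <- "artic_model"
dict_format_tag <- "artic_diphone_dictionary"

read_json_container <- function(path, expected_format) {
  if (!file.exists(path)) abort_artic("file does not exist: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    abort_artic("not a valid %s file (%s): %s",
                                expected_format, path, conditionMessage(e)))
  if (!identical(obj$format, expected_format))
    abort_artic("schema mismatch in %s: expected format '%s', found '%s'",
                path, expected_format, obj$format %||% "<none>")
  if (is.null(obj$version) || obj$version != 1)
    abort_artic("unsupported %s schema version in %s", expected_format, path)
  obj
}

#' Save an articulatory model to JSON
#'
#' @param model an `artmodel` (from [fit_guided_pca()] or loaded).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "artmodel"))
  obj <- list(format = model_format_tag, version = 1L,
              coords = model$coords,
              parameter_names = model$parameter_names,
              mean = unname(model$mean),
              loadings = unname(model$loadings),
              variance_fractions = unname(model$variance_fractions),
              total_variance = model$total_variance,
              n_frames = model$n_frames,
              scheme_steps = model$scheme$steps,
              scheme_signs = unname(model$scheme$signs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load an articulatory model from JSON
#'
#' @param path file written by [save_model()].
#' @return The `artmodel`.
#' @export
load_model <- function(path) {
  obj <- read_json_container(path, model_format_tag)
  M <- length(obj$parameter_names)
  loadings <- matrix(unlist(obj$loadings) %||% numeric(0),
                     length(obj$coords), M)
  scheme <- if (M > 0L)
    extraction_scheme(lapply(obj$scheme_steps, unlist),
                      stats::setNames(unlist(obj$scheme_signs),
                                      names(obj$scheme_steps)))
  else NULL
  new_artmodel(unlist(obj$mean), loadings,
               as.character(unlist(obj$parameter_names)),
               stats::setNames(unlist(obj$variance_fractions),
                               unlist(obj$parameter_names)),
               obj$total_variance, scheme,
               as.character(unlist(obj$coords)),
               n_frames = obj$n_frames %||% NA_integer_)
}

#' Save a diphone dictionary to JSON
#'
#' Unit provenance (source utterance, frame range) is preserved exactly.
#'
#' @param dict a [build_dictionary()] dictionary.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "diphone_dictionary"))
  units <- list()
  for (lab in names(dict)) {
    for (u in dict[[lab]]) {
      units[[length(units) + 1L]] <- list(
        label = u$label,
        source_utterance = u$source_utterance,
        source_frames = u$source_frames,
        duration = u$duration,
        rate = traj_rate(u$trajectory),
        parameter_names = rownames(u$trajectory),
        values = unclass(u$trajectory))
    }
  }
  obj <- list(format = dict_format_tag, version = 1L, units = units)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null",
                       simplifyVector = FALSE)
  invisible(path)
}

#' Load a diphone dictionary from JSON
#'
#' @param path file written by [save_dictionary()].
#' @return The `diphone_dictionary`.
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) abort_artic("file does not exist: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    abort_artic("not a valid %s file (%s): %s",
                                dict_format_tag, path, conditionMessage(e)))
  if (!identical(obj$format, dict_format_tag))
    abort_artic("schema mismatch in %s: expected format '%s'",
                path, dict_format_tag)
  if (is.null(obj$version) || obj$version != 1)
    abort_artic("unsupported dictionary schema version in %s", path)
  units <- lapply(obj$units, function(u) {
    pn <- as.character(unlist(u$parameter_names))
    vals <- do.call(rbind, lapply(u$values, unlist))
    if (is.null(vals)) vals <- matrix(0, length(pn), 0L)
    diphone_unit(u$label,
                 trajectory_matrix(vals, u$rate, pn),
                 u$source_utterance,
                 unlist(u$source_frames),
                 duration = u$duration)
  })
  labels <- vapply(units, function(u) u$label, "")
  dict <- split(units, factor(labels, levels = unique(sort(labels))))
  structure(dict, class = "diphone_dictionary")
}

#' Write a sensor series as CSV
#'
#' One row per frame: `time`, then `sensor.x, sensor.y, sensor.z` per
#' sensor.  Missing samples are written as empty fields.
#'
#' @param series a [sensor_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_series <- function(series, path) {
  mat <- series_matrix(series)
  vis <- series$mask[, rep(seq_along(series$sensor_names), each = 3L),
                     drop = FALSE]
  mat[!vis] <- NA_real_
  df <- data.frame(time = series$times, mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a sensor series from CSV
#'
#' @param path file written by [write_sensor_series()].
#' @return A [sensor_series()]; empty fields become masked samples (a
#'   sensor sample is masked if any of its three coordinates is missing),
#'   with positions at masked samples filled by linear interpolation.
#' @export
read_sensor_series <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  t <- df[[1L]]
  if (length(t) < 2L) abort_artic("sensor CSV must contain >= 2 frames")
  dt <- diff(t)
  if (max(abs(dt - dt[1L])) > 1e-6)
    abort_artic("sensor CSV times are not uniformly spaced")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  cols <- colnames(mat)
  sensors <- unique(sub("\\.[xyz]$", "", cols))
  if (!identical(cols, coord_names(sensors)))
    abort_artic("sensor CSV columns must be sensor.x/.y/.z triplets")
  mask <- matrix(TRUE, nrow(mat), length(sensors))
  for (j in seq_along(sensors)) {
    block <- mat[, 3L * j - 2:0, drop = FALSE]
    mask[, j] <- rowSums(is.na(block)) == 0L
  }
  for (j in seq_len(ncol(mat))) {
    v <- !is.na(mat[, j])
    mat[, j] <- fill_gaps(ifelse(v, mat[, j], 0), v)
  }
  matrix_to_series(mat, 1 / dt[1L], sensors, times = t, mask = mask)
}
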