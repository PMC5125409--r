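# Diphone inventory derivation and the multimodal diphone dictionary.
#
# A diphone spans from the temporal midpoint of one phone to the midpoint
# of the next -- the steadiest part of each allophone -- so concatenation
# joins happen where the articulators move least.  Midpoint times map to
# frame indices as floor(time * rate); units are half-open [start, end) in
# 0-based frames, so a sentence's units partition its frames exactly.

#' Derive the diphone target list of a segmentation
#'
#' @param seg a [phone_segmentation()] with at least 2 phones.
#' @return A data frame of class `diphone_targets` with columns `label`
#'   (two SAMPA symbols pasted together), `duration` (seconds, midpoint to
#'   midpoint), `start` and `end` (midpoint times).
#' @examples
#' seg <- phone_segmentation(c("_", "w", "E", "l", "k", "@", "m", "_"),
#'                           c(0.060, 0.125, 0.19, 0.29, 0.385, 0.51, 0.695, 0.8))
#' phones_to_diphones(seg)$label
#' @export
phones_to_diphones <- function(seg) {
  stopifnot(inherits(seg, "phone_segmentation"))
  n <- nrow(seg)
  if (n < 2L)
    abort_artic("need at least 2 phones to derive diphones (got %d)", n)
  mid <- segmentation_midpoints(seg)
  out <- data.frame(
    label = paste0(seg$label[-n], seg$label[-1L]),
    duration = diff(mid),
    start = mid[-n],
    end = mid[-1L],
    stringsAsFactors = FALSE)
  class(out) <- c("diphone_targets", "data.frame")
  out
}

#' Create a diphone unit
#'
#' @param label diphone label (two SAMPA symbols).
#' @param trajectory a [trajectory_matrix()] slice with at least one frame.
#' @param source_utterance utterance id the unit came from.
#' @param source_frames integer `(start, end)` half-open 0-based frame
#'   range in the source trajectory.
#' @param duration unit duration in seconds; defaults to
#'   `frames / rate`.
#' @return An object of class `diphone_unit`.
#' @export
diphone_unit <- function(label, trajectory, source_utterance,
                         source_frames, duration = NULL) {
  stopifnot(inherits(trajectory, "trajectory_matrix"))
  if (ncol(trajectory) < 1L)
    abort_artic("diphone unit '%s' has no frames", label)
  source_frames <- as.integer(source_frames)
  if (length(source_frames) != 2L ||
      source_frames[2L] - source_frames[1L] != ncol(trajectory))
    abort_artic("source_frames must be half-open and match the %d-frame trajectory",
                ncol(trajectory))
  structure(list(label = label, trajectory = trajectory,
                 source_utterance = as.character(source_utterance),
                 source_frames = source_frames,
                 duration = duration %||% (ncol(trajectory) / traj_rate(trajectory))),
            class = "diphone_unit")
}

#' @export
print.diphone_unit <- function(x, ...) {
  cat(sprintf("Diphone unit '%s': %d frames (%.3f s) from %s[%d, %d)\n",
              x$label, ncol(x$trajectory), x$duration, x$source_utterance,
              x$source_frames[1L], x$source_frames[2L]))
  invisible(x)
}

#' Cut a trajectory into diphone units along a segmentation
#'
#' @param seg the utterance's [phone_segmentation()].
#' @param traj the utterance's [trajectory_matrix()] (same clock, starting
#'   at time 0).
#' @return List of [diphone_unit()]s whose frame ranges tile the span from
#'   the first to the last phone midpoint.
#' @export
extract_diphone_units <- function(seg, traj) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  targets <- phones_to_diphones(seg)
  rate <- traj_rate(traj)
  mid <- segmentation_midpoints(seg)
  f <- as.integer(floor(mid * rate + 1e-9))
  if (any(diff(f) < 1L))
    abort_artic("phones too short: adjacent midpoints map to the same %g Hz frame",
                rate)
  if (f[length(f)] > ncol(traj))
    abort_artic("trajectory (%d frames) shorter than the segmentation needs (%d)",
                ncol(traj), f[length(f)])
  lapply(seq_len(nrow(targets)), function(i) {
    cols <- (f[i] + 1L):f[i + 1L]      # 0-based [f_i, f_{i+1}) -> 1-based
    diphone_unit(targets$label[i], traj_slice(traj, cols),
                 utterance_id(seg), c(f[i], f[i + 1L]),
                 duration = targets$duration[i])
  })
}

#' Build a diphone dictionary from a corpus
#'
#' @param corpus list of entries, each a list with elements `seg` (a
#'   [phone_segmentation()]) and `traj` (a [trajectory_matrix()]).
#' @return An object of class `diphone_dictionary`: a named list mapping
#'   each diphone label to its list of [diphone_unit()]s, sorted stably by
#'   source utterance id and frame start.
#' @export
build_dictionary <- function(corpus) {
  if (length(corpus) == 0L)
    abort_artic("corpus is empty")
  units <- list()
  for (entry in corpus) {
    us <- extract_diphone_units(entry$seg, entry$traj)
    for (u in us) units[[length(units) + 1L]] <- u
  }
  labels <- vapply(units, function(u) u$label, "")
  dict <- split(units, factor(labels, levels = unique(sort(labels))))
  dict <- lapply(dict, function(us) {
    ord <- order(vapply(us, function(u) u$source_utterance, ""),
                 vapply(us, function(u) u$source_frames[1L], 0L))
    us[ord]
  })
  structure(dict, class = "diphone_dictionary")
}

#' @export
print.diphone_dictionary <- function(x, ...) {
  n_units <- sum(vapply(x, length, 1L))
  cat(sprintf("Diphone dictionary: %d labels, %d units\n", length(x), n_units))
  invisible(x)
}

#' Coverage report of a diphone dictionary
#' @param dict a `diphone_dictionary`.
#' @return Data frame with columns `label` and `n_units`.
#' @export
dictionary_coverage <- function(dict) {
  data.frame(label = names(dict),
             n_units = vapply(dict, length, 1L),
             row.names = NULL)
}
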