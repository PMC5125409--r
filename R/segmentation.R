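# Phone segmentations: ordered (SAMPA label, end time) intervals for one
# utterance.  Interval i spans [end_{i-1}, end_i) with the first interval
# starting at 0; the silence label is "_".

#' Create a phone segmentation
#'
#' A phone segmentation is the timing skeleton of one utterance: an ordered
#' sequence of SAMPA phone labels with their interval end times in seconds.
#' The first interval starts at time 0 and intervals are half-open
#' `[start, end)`.  Silence is labelled `"_"`.
#'
#' @param labels character vector of SAMPA phone labels (non-empty strings).
#' @param end_times numeric vector of strictly increasing interval end times
#'   in seconds; the last value is the utterance duration.
#' @param utterance_id identifier for the utterance the segmentation
#'   belongs to.
#' @return An object of class `phone_segmentation`: a data frame with
#'   columns `label` and `end`, and an `utterance_id` attribute.
#' @examples
#' seg <- phone_segmentation(c("_", "w", "E", "l", "k", "@", "m", "_"),
#'                           c(0.060, 0.125, 0.19, 0.29, 0.385, 0.51, 0.695, 0.8),
#'                           utterance_id = "welcome")
#' seg
#' @seealso [read_segmentation()], [write_segmentation()],
#'   [phones_to_diphones()]
#' @export
phone_segmentation <- function(labels, end_times, utterance_id = "utt") {
  labels <- as.character(labels)
  end_times <- as.numeric(end_times)
  if (length(labels) == 0L)
    abort_artic("segmentation must contain at least one interval")
  if (length(labels) != length(end_times))
    abort_artic("'labels' and 'end_times' must have the same length (%d vs %d)",
                length(labels), length(end_times))
  if (any(!nzchar(labels)) || anyNA(labels))
    abort_artic("phone labels must be non-empty strings")
  if (anyNA(end_times) || any(!is.finite(end_times)))
    abort_artic("end times must be finite")
  if (end_times[1L] <= 0)
    abort_artic("first interval must end after time 0 (got %g)", end_times[1L])
  if (length(end_times) > 1L && any(diff(end_times) <= 0))
    abort_artic("end times must be strictly increasing (violated at interval %d)",
                which(diff(end_times) <= 0)[1L] + 1L)
  out <- data.frame(label = labels, end = end_times, stringsAsFactors = FALSE)
  attr(out, "utterance_id") <- as.character(utterance_id)
  class(out) <- c("phone_segmentation", "data.frame")
  out
}

#' @export
print.phone_segmentation <- function(x, ...) {
  cat(sprintf("Phone segmentation '%s': %d intervals, %.3f s\n",
              utterance_id(x), nrow(x), x$end[nrow(x)]))
  starts <- c(0, x$end[-nrow(x)])
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%7.3f, %7.3f)  %s\n", starts[i], x$end[i], x$label[i]))
  invisible(x)
}

#' Utterance identifier of a segmentation
#' @param x a `phone_segmentation`.
#' @return The utterance id as a string.
#' @export
utterance_id <- function(x) attr(x, "utterance_id") %||% "utt"

#' Interval start times of a segmentation
#' @param seg a `phone_segmentation`.
#' @return Numeric vector of interval start times (first is 0).
#' @export
segmentation_starts <- function(seg) c(0, seg$end[-nrow(seg)])

#' Phone midpoint times of a segmentation
#'
#' Midpoints of the half-open phone intervals; diphone units span from one
#' phone midpoint (the steadiest part of the allophone) to the next.
#' @param seg a `phone_segmentation`.
#' @return Numeric vector of midpoint times in seconds, one per phone.
#' @export
segmentation_midpoints <- function(seg) {
  (segmentation_starts(seg) + seg$end) / 2
}

#' Read a phone segmentation file
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{`"lab"`}{festvox-style label files: one interval per line,
#'     `"end_time_seconds label"`, header lines starting with `#` ignored.}
#'   \item{`"textgrid"`}{Praat long TextGrid text format; the first
#'     IntervalTier is used.}
#' }
#' Both dialects store end times in seconds; the 0-start convention is
#' enforced on read.
#'
#' @param path path to the file.
#' @param dialect `"lab"` or `"textgrid"`.
#' @param utterance_id id recorded on the returned object; defaults to the
#'   file name without extension.
#' @return A [phone_segmentation()].
#' @export
read_segmentation <- function(path, dialect = c("lab", "textgrid"),
                              utterance_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    abort_artic("segmentation file does not exist: %s", path)
  if (is.null(utterance_id))
    utterance_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "lab") {
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (length(keep) == 0L)
      abort_artic("no intervals found in lab file %s", path)
    ends <- numeric(length(keep))
    labs <- character(length(keep))
    for (i in seq_along(keep)) {
      fields <- strsplit(trimws(lines[keep[i]]), "\\s+")[[1L]]
      if (length(fields) < 2L)
        abort_artic("malformed lab line %d in %s: '%s'",
                    keep[i], path, lines[keep[i]])
      t <- suppressWarnings(as.numeric(fields[1L]))
      if (is.na(t))
        abort_artic("unparseable time on lab line %d in %s", keep[i], path)
      ends[i] <- t
      labs[i] <- fields[2L]
    }
    return(phone_segmentation(labs, ends, utterance_id))
  }
  # Praat long TextGrid: first IntervalTier only
  tier_starts <- grep("class\\s*=\\s*\"IntervalTier\"", lines)
  if (length(tier_starts) == 0L)
    abort_artic("no IntervalTier found in TextGrid %s", path)
  from <- tier_starts[1L]
  to <- if (length(tier_starts) > 1L) tier_starts[2L] - 1L else length(lines)
  block <- lines[from:to]
  iv <- grep("intervals\\s*\\[", block)
  if (length(iv) == 0L)
    abort_artic("IntervalTier in %s contains no intervals", path)
  num_field <- function(ls, key) {
    hit <- grep(paste0("^\\s*", key, "\\s*="), ls, value = TRUE)[1L]
    if (is.na(hit)) return(NA_real_)
    suppressWarnings(as.numeric(sub(".*=\\s*", "", hit)))
  }
  txt_field <- function(ls) {
    hit <- grep("^\\s*text\\s*=", ls, value = TRUE)[1L]
    if (is.na(hit)) return(NA_character_)
    m <- sub("^\\s*text\\s*=\\s*\"(.*)\"\\s*$", "\\1", hit)
    gsub("\"\"", "\"", m)
  }
  bounds <- c(iv, length(block) + 1L)
  ends <- numeric(length(iv))
  labs <- character(length(iv))
  for (i in seq_along(iv)) {
    chunk <- block[bounds[i]:(bounds[i + 1L] - 1L)]
    xmax <- num_field(chunk, "xmax")
    if (is.na(xmax))
      abort_artic("interval %d in %s lacks an xmax (near line %d)",
                  i, path, from + bounds[i] - 1L)
    ends[i] <- xmax
    lab <- txt_field(chunk)
    labs[i] <- if (is.na(lab) || !nzchar(lab)) "_" else lab
  }
  phone_segmentation(labs, ends, utterance_id)
}

#' Write a phone segmentation file
#'
#' Inverse of [read_segmentation()]: writing then reading returns an
#' identical segmentation.
#'
#' @param seg a [phone_segmentation()].
#' @param path output path.
#' @param dialect `"lab"` or `"textgrid"` (see [read_segmentation()]).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path, dialect = c("lab", "textgrid")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(seg, "phone_segmentation"))
  if (dialect == "lab") {
    lines <- c("# lab segmentation",
               sprintf("%.17g %s", seg$end, seg$label))
    writeLines(lines, path)
    return(invisible(path))
  }
  starts <- segmentation_starts(seg)
  n <- nrow(seg)
  lines <- c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    "xmin = 0",
    sprintf("xmax = %.17g", seg$end[n]),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    "        class = \"IntervalTier\"",
    "        name = \"phones\"",
    "        xmin = 0",
    sprintf("        xmax = %.17g", seg$end[n]),
    sprintf("        intervals: size = %d", n))
  for (i in seq_len(n)) {
    lines <- c(lines,
               sprintf("        intervals [%d]:", i),
               sprintf("            xmin = %.17g", starts[i]),
               sprintf("            xmax = %.17g", seg$end[i]),
               sprintf("            text = \"%s\"",
                       gsub("\"", "\"\"", seg$label[i])))
  }
  writeLines(lines, path)
  invisible(path)
}
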