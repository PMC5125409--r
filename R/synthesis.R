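# Visual synthesis by diphone unit selection and gapless concatenation.
#
# Given a phone + duration list and a diphone dictionary, the synthesizer
# (1) derives diphone targets, (2) selects the best candidate series
# through a trellis by dynamic programming on concatenation cost (RMS
# parameter mismatch at each join; zero for units that are contiguous in
# their source utterance), (3) linearly time-warps each unit to its target
# duration, and (4) removes the residual joins by a linear in-unit ramp so
# that the last sample of each unit coincides with the first sample of the
# next, while second differences -- the nonlinear shape of the movement --
# are preserved exactly.

#' Derive diphone targets from a phone + duration list
#'
#' @param phones character vector of SAMPA labels (at least 2).
#' @param durations phone durations in seconds (positive, one per phone).
#' @return A `diphone_targets` data frame (see [phones_to_diphones()]).
#' @export
assemble_target_sequence <- function(phones, durations) {
  if (length(phones) < 2L)
    abort_artic("need at least 2 phones to synthesize (got %d)",
                length(phones))
  if (length(durations) != length(phones))
    abort_artic("need one duration per phone")
  if (any(!is.finite(durations)) || any(durations <= 0))
    abort_artic("phone durations must be positive")
  phones_to_diphones(phone_segmentation(phones, cumsum(durations),
                                        utterance_id = "target"))
}

boundary_cost <- function(u, v) {
  if (is_contiguous(u, v)) return(0)
  du <- v$trajectory[, 1L] - u$trajectory[, ncol(u$trajectory)]
  sqrt(mean(du^2))
}

is_contiguous <- function(u, v) {
  !is_bridge(u) && !is_bridge(v) &&
    u$source_utterance == v$source_utterance &&
    u$source_frames[2L] == v$source_frames[1L]
}

is_bridge <- function(u) isTRUE(u$bridge)

#' Select the best diphone unit series through the candidate trellis
#'
#' Builds the per-slot candidate lists from the dictionary and finds, by
#' dynamic programming, the series minimizing
#' `sum(boundary RMS) + w_sel * sum(|log(unit_duration / target_duration)|)`.
#' Consecutive candidates that are contiguous in their source utterance
#' cost nothing at the join.  A target with no unit of its own falls back
#' to units sharing its second phone; if none exist the slot is filled
#' after selection with a 2-frame linear bridge between its neighbours'
#' boundary postures (with a warning).  Ties are broken toward the lowest
#' candidate index, which is stable in source utterance order.
#'
#' @param targets a `diphone_targets` data frame.
#' @param dict a [build_dictionary()] dictionary.
#' @param w_sel weight of the duration (selection) penalty; default 0 so
#'   selection is driven by concatenation cost alone.
#' @return List of selected [diphone_unit()]s (bridges carry
#'   `source_utterance = "<bridge>"`), with the total cost in attribute
#'   `"cost"`.
#' @export
select_units <- function(targets, dict, w_sel = 0) {
  stopifnot(inherits(dict, "diphone_dictionary"))
  S <- nrow(targets)
  if (S == 0L) abort_artic("no diphone targets")
  slots <- vector("list", S)
  bridged <- logical(S)
  for (s in seq_len(S)) {
    lab <- targets$label[s]
    cands <- dict[[lab]]
    if (is.null(cands) || length(cands) == 0L) {
      second <- substring(lab, nchar(lab))
      pool <- unlist(lapply(names(dict), function(l) {
        if (substring(l, nchar(l)) == second) dict[[l]] else NULL
      }), recursive = FALSE)
      if (length(pool)) {
        cands <- pool
      } else {
        bridged[s] <- TRUE
        cands <- list(structure(list(label = lab, bridge = TRUE),
                                class = "diphone_unit"))
        warning(sprintf("no unit for diphone '%s'; inserting a linear bridge",
                        lab), call. = FALSE)
      }
    }
    slots[[s]] <- cands
  }
  node_cost <- function(s, u) {
    if (is_bridge(u) || w_sel == 0) return(0)
    w_sel * abs(log(u$duration / targets$duration[s]))
  }
  trans_cost <- function(u, v) {
    if (is_bridge(u) || is_bridge(v)) return(0)
    boundary_cost(u, v)
  }
  # forward DP, earliest-index tie-break via strict improvement
  best <- lapply(slots[[1L]], function(u) node_cost(1L, u))
  back <- vector("list", S)
  for (s in seq_len(S - 1L)) {
    nxt <- slots[[s + 1L]]
    nb <- numeric(length(nxt)); bp <- integer(length(nxt))
    for (j in seq_along(nxt)) {
      bcost <- Inf; bprev <- 1L
      for (i in seq_along(slots[[s]])) {
        v <- best[[i]] + trans_cost(slots[[s]][[i]], nxt[[j]])
        if (v < bcost) { bcost <- v; bprev <- i }
      }
      nb[j] <- bcost + node_cost(s + 1L, nxt[[j]])
      bp[j] <- bprev
    }
    best <- as.list(nb)
    back[[s + 1L]] <- bp
  }
  last <- which.min(unlist(best))
  path <- integer(S); path[S] <- last
  for (s in rev(seq_len(S - 1L))) path[s] <- back[[s + 1L]][path[s + 1L]]
  selected <- lapply(seq_len(S), function(s) slots[[s]][[path[s]]])
  # materialize bridges between the selected neighbours
  for (s in which(bridged)) {
    left <- if (s > 1L && !is_bridge(selected[[s - 1L]]))
      selected[[s - 1L]]$trajectory[, ncol(selected[[s - 1L]]$trajectory)]
    else NULL
    right <- if (s < S && !is_bridge(selected[[s + 1L]]))
      selected[[s + 1L]]$trajectory[, 1L] else NULL
    if (is.null(left) && is.null(right))
      abort_artic("cannot bridge diphone '%s': no resolvable neighbours",
                  targets$label[s])
    left <- left %||% right
    right <- right %||% left
    ref <- selected[[if (s > 1L) s - 1L else s + 1L]]$trajectory
    vals <- cbind(left, right)
    rownames(vals) <- rownames(ref)
    selected[[s]] <- diphone_unit(targets$label[s],
                                  trajectory_matrix(vals, traj_rate(ref)),
                                  "<bridge>", c(0L, 2L),
                                  duration = targets$duration[s])
  }
  total <- unlist(best)[last]
  attr(selected, "cost") <- total
  selected
}

#' Warp a diphone unit to a target duration
#'
#' Linear time rescaling: the trajectory is resampled at `rate` on a
#' uniformly stretched time axis.  First and last frame values are
#' preserved exactly, and a linear ramp stays a linear ramp.
#'
#' @param unit a [diphone_unit()].
#' @param target_duration desired duration in seconds.
#' @param rate output frame rate in Hz (default 60).
#' @return The warped [diphone_unit()] (same provenance).
#' @export
warp_unit_duration <- function(unit, target_duration, rate = 60) {
  check_scalar(target_duration, "target_duration", positive = TRUE)
  vals <- unclass(unit$trajectory)
  n_in <- ncol(vals)
  n_out <- max(1L, as.integer(round_half_up(target_duration * rate)))
  if (n_in == 1L) {
    out <- vals[, rep(1L, n_out), drop = FALSE]
  } else if (n_out == 1L) {
    out <- vals[, 1L, drop = FALSE]
  } else {
    x_in <- seq(0, 1, length.out = n_in)
    x_out <- seq(0, 1, length.out = n_out)
    out <- t(apply(vals, 1L, function(row)
      stats::approx(x_in, row, xout = x_out)$y))
    # guard round-off at the endpoints
    out[, 1L] <- vals[, 1L]
    out[, n_out] <- vals[, n_in]
  }
  u <- unit
  u$trajectory <- trajectory_matrix(out, rate, rownames(vals))
  u$duration <- target_duration
  u
}

#' Concatenate diphone units without boundary gaps
#'
#' At every join where the two units are not contiguous in their source
#' utterance, the concatenation gap `delta` (first frame of the next unit
#' minus last frame of the current one, per parameter) is removed by adding
#' `delta * i / T` to frame `i = 1..T` of the current unit, so its last
#' frame comes to coincide with the next unit's first frame; the duplicated
#' boundary frame is then dropped.  Joins are processed from the last
#' boundary backwards so that every join is exact after processing.  The
#' ramp is linear in time, so within-unit second differences -- the
#' nonlinear shape of the articulation -- are unchanged.  Joins between
#' source-contiguous units are genuine trajectory and are concatenated
#' as-is.
#'
#' @param units list of [diphone_unit()]s sharing parameter set and rate.
#' @return A [trajectory_matrix()]; attribute `"boundary_audit"` holds a
#'   data frame with per-join `contiguous` flags and post-processing
#'   `mismatch` values.
#' @export
gapless_concatenate <- function(units) {
  if (length(units) == 0L) abort_artic("no units to concatenate")
  rate <- traj_rate(units[[1L]]$trajectory)
  pn <- rownames(units[[1L]]$trajectory)
  for (u in units) {
    if (!identical(rownames(u$trajectory), pn))
      abort_artic("units disagree on the parameter set")
    if (abs(traj_rate(u$trajectory) - rate) > 1e-9)
      abort_artic("units disagree on the frame rate")
  }
  vals <- lapply(units, function(u) unclass(u$trajectory))
  n <- length(units)
  contig <- logical(max(n - 1L, 0L))
  if (n > 1L) {
    for (s in seq_len(n - 1L))
      contig[s] <- is_contiguous(units[[s]], units[[s + 1L]])
    for (s in rev(seq_len(n - 1L))) {
      if (contig[s]) next
      Tcur <- ncol(vals[[s]])
      delta <- vals[[s + 1L]][, 1L] - vals[[s]][, Tcur]
      ramp <- outer(delta, seq_len(Tcur) / Tcur)
      vals[[s]] <- vals[[s]] + ramp
    }
  }
  mismatch <- numeric(max(n - 1L, 0L))
  pieces <- vector("list", n)
  pieces[[1L]] <- vals[[1L]]
  if (n > 1L) {
    for (s in seq_len(n - 1L)) {
      nxt <- vals[[s + 1L]]
      mismatch[s] <- max(abs(nxt[, 1L] - vals[[s]][, ncol(vals[[s]])]))
      # drop the duplicated boundary frame at processed joins
      pieces[[s + 1L]] <- if (contig[s]) nxt else nxt[, -1L, drop = FALSE]
    }
  }
  out <- trajectory_matrix(do.call(cbind, pieces), rate, pn)
  attr(out, "boundary_audit") <- data.frame(
    join = seq_len(max(n - 1L, 0L)),
    contiguous = contig, mismatch = mismatch)
  out
}

#' Synthesize articulatory trajectories for a phone + duration list
#'
#' Full visual-synthesis pipeline: derive diphone targets, select units
#' from the dictionary, warp each unit to its target duration, concatenate
#' gaplessly and clip to the parameter box.
#'
#' @param phones character vector of SAMPA labels.
#' @param durations phone durations in seconds.
#' @param dict a [build_dictionary()] dictionary.
#' @param rate output frame rate in Hz (default 60).
#' @param w_sel duration-penalty weight passed to [select_units()].
#' @param bounds final clipping box (default `c(-3, 3)`), or `NULL`.
#' @return A [trajectory_matrix()] at `rate`; attributes `"units"` (the
#'   selected units), `"cost"` (selection cost) and `"boundary_audit"`
#'   (from [gapless_concatenate()]).
#' @export
synthesize_trajectories <- function(phones, durations, dict, rate = 60,
                                    w_sel = 0, bounds = c(-3, 3)) {
  targets <- assemble_target_sequence(phones, durations)
  selected <- select_units(targets, dict, w_sel = w_sel)
  warped <- lapply(seq_along(selected), function(s)
    warp_unit_duration(selected[[s]], targets$duration[s], rate = rate))
  out <- gapless_concatenate(warped)
  audit <- attr(out, "boundary_audit")
  if (!is.null(bounds)) {
    clipped <- pmin(pmax(unclass(out), bounds[1L]), bounds[2L])
    out <- trajectory_matrix(clipped, rate, rownames(out))
  }
  attr(out, "units") <- selected
  attr(out, "cost") <- attr(selected, "cost")
  attr(out, "boundary_audit") <- audit
  out
}
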