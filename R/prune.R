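# Frame pruning (simple vector quantization): drop frames whose stacked
# sensor coordinates are within min_dist (mm, Euclidean) of an already-kept
# frame.  Greedy, first-come, in time order -- deterministic and
# order-stable.

#' Prune near-duplicate frames before model fitting
#'
#' Scans frames in time order and keeps a frame iff its stacked-coordinate
#' Euclidean distance to every already-kept frame is at least `min_dist`.
#' This conditions the data for statistical modelling: long steady
#' stretches (silences, holds) would otherwise dominate the variance.
#'
#' @param x a [sensor_series()], or a numeric `(frames, coordinates)`
#'   matrix.
#' @param min_dist minimum pairwise distance in mm (default 1.0).  With
#'   `min_dist = 0` every frame is kept.
#' @return An object of class `quantized_frames`: list with `coords`
#'   (kept frames x coordinates matrix, named columns), `index` (kept frame
#'   indices into the input) and `min_dist`.
#' @export
prune_frames <- function(x, min_dist = 1.0) {
  if (inherits(x, "sensor_series")) {
    mat <- series_matrix(x)
    ok <- rowSums(!x$mask) == 0L
    mat <- mat[ok, , drop = FALSE]
    orig <- which(ok)
  } else {
    mat <- as.matrix(x)
    orig <- seq_len(nrow(mat))
  }
  n <- nrow(mat)
  if (n == 0L)
    return(structure(list(coords = mat, index = integer(0),
                          min_dist = min_dist),
                     class = "quantized_frames"))
  if (min_dist <= 0) {
    return(structure(list(coords = mat, index = orig, min_dist = min_dist),
                     class = "quantized_frames"))
  }
  d2min <- min_dist^2
  keep <- logical(n)
  kept_rows <- matrix(0, 0L, ncol(mat))
  kept_sq <- numeric(0)
  row_sq <- rowSums(mat^2)
  block <- 512L
  start <- 1L
  while (start <= n) {
    end <- min(n, start + block - 1L)
    idx <- start:end
    B <- mat[idx, , drop = FALSE]
    # squared distances to frames kept in earlier blocks, via one GEMM
    if (nrow(kept_rows)) {
      cross <- B %*% t(kept_rows)
      d2 <- outer(row_sq[idx], kept_sq, `+`) - 2 * cross
      near_prev <- rowSums(d2 < d2min) > 0L
    } else near_prev <- rep(FALSE, length(idx))
    # within-block greedy pass
    local_kept <- integer(0)
    for (k in seq_along(idx)) {
      if (near_prev[k]) next
      if (length(local_kept)) {
        diff <- B[local_kept, , drop = FALSE] -
          rep(B[k, ], each = length(local_kept))
        if (any(rowSums(diff^2) < d2min)) next
      }
      local_kept <- c(local_kept, k)
      keep[idx[k]] <- TRUE
    }
    if (length(local_kept)) {
      kept_rows <- rbind(kept_rows, B[local_kept, , drop = FALSE])
      kept_sq <- c(kept_sq, row_sq[idx[local_kept]])
    }
    start <- end + 1L
  }
  structure(list(coords = mat[keep, , drop = FALSE], index = orig[keep],
                 min_dist = min_dist),
            class = "quantized_frames")
}

#' @export
print.quantized_frames <- function(x, ...) {
  cat(sprintf("Quantized frame set: %d frames x %d coordinates (min_dist %g mm)\n",
              nrow(x$coords), ncol(x$coords), x$min_dist))
  invisible(x)
}
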