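# Unit selection, duration warping and gapless concatenation.

test_that("target assembly mirrors diphone derivation on cumulative timing", {
  targets <- assemble_target_sequence(
    c("_", "w", "E", "l", "k", "@", "m", "_"),
    diff(c(0, 0.060, 0.125, 0.19, 0.29, 0.385, 0.51, 0.695, 0.8)))
  expect_equal(targets$label, c("_w", "wE", "El", "lk", "k@", "@m", "m_"))
  two <- assemble_target_sequence(c("a", "b"), c(0.2, 0.2))
  expect_equal(two$duration, 0.2)
  expect_error(assemble_target_sequence("a", 0.2), "at least 2")
  expect_error(assemble_target_sequence(c("a", "b"), c(0.2, -1)), "positive")
})

test_that("a single-candidate trellis returns the summed boundary cost", {
  set.seed(70)
  slots <- lapply(1:4, function(s) list(random_unit(paste0("l", s), "u", s * 10, 4)))
  dict <- structure(stats::setNames(slots, paste0("l", 1:4)),
                    class = "diphone_dictionary")
  targets <- data.frame(label = paste0("l", 1:4), duration = 0.1,
                        start = 0, end = 0.1)
  class(targets) <- c("diphone_targets", "data.frame")
  sel <- select_units(targets, dict)
  manual <- sum(vapply(1:3, function(s)
    artic:::boundary_cost(sel[[s]], sel[[s + 1]]), 0))
  expect_equal(attr(sel, "cost"), manual, tolerance = 1e-12)
})

test_that("dynamic programming equals exhaustive search on random trellises", {
  set.seed(71)
  labs <- c("ab", "bc", "cd", "de", "ef")
  for (trial in 1:40) {
    S <- sample(2:5, 1); K <- sample(1:4, 1)
    slots <- lapply(1:S, function(s)
      lapply(1:K, function(k)
        random_unit(labs[s], sprintf("u%d", k), sample(0:60, 1),
                    sample(2:6, 1))))
    dict <- structure(stats::setNames(slots, labs[1:S]),
                      class = "diphone_dictionary")
    targets <- data.frame(label = labs[1:S], duration = 0.1,
                          start = 0, end = 0.1)
    class(targets) <- c("diphone_targets", "data.frame")
    sel <- select_units(targets, dict)
    ex <- exhaustive_selection(slots)
    expect_equal(attr(sel, "cost"), ex$cost, tolerance = 1e-10)
  }
})

test_that("a sentence's own contiguous units are selected at zero cost", {
  set.seed(72)
  seg <- phone_segmentation(c("_", "E", "l", "k", "_"),
                            c(0.2, 0.4, 0.6, 0.8, 1.0), "self")
  traj <- trajectory_matrix(matrix(rnorm(3 * 60), 3, 60), 60)
  own <- list(seg = seg, traj = traj)
  dict <- build_dictionary(list(own))
  targets <- phones_to_diphones(seg)
  # decoy candidates, each from a different utterance, so any decoy path
  # pays a non-zero concatenation cost
  for (s in seq_len(nrow(targets))) {
    lab <- targets$label[s]
    dict[[lab]] <- c(dict[[lab]],
                     list(random_unit(lab, sprintf("decoy%d", s),
                                      s * 10, 5)))
  }
  sel <- select_units(targets, dict)
  expect_equal(attr(sel, "cost"), 0, tolerance = 1e-12)
  expect_true(all(vapply(sel, function(u) u$source_utterance, "") == "self"))
})

test_that("warping preserves endpoints, linearity and frame-count arithmetic", {
  u <- random_unit("ab", "u", 0, 10)
  same <- warp_unit_duration(u, 10 / 60)
  expect_equal(unclass(same$trajectory), unclass(u$trajectory),
               tolerance = 1e-12)
  ramp <- diphone_unit("ab", trajectory_matrix(
    matrix(seq(0, 1, length.out = 6), 1, 6), 60), "u", c(0, 6))
  stretched <- warp_unit_duration(ramp, 12 / 60)
  vals <- unclass(stretched$trajectory)[1, ]
  expect_equal(ncol(stretched$trajectory), 12L)
  expect_equal(vals[1], 0); expect_equal(vals[12], 1)
  expect_lt(max(abs(diff(vals) - diff(vals)[1])), 1e-12)  # still linear
  five <- warp_unit_duration(random_unit("ab", "u", 0, 10), 0.083)
  expect_equal(ncol(five$trajectory), 5L)   # round(0.083 * 60) = 5
})

test_that("the gapless ramp reproduces the hand-computed example", {
  u1 <- diphone_unit("ab", trajectory_matrix(matrix(0, 1, 4), 60),
                     "u1", c(0, 4))
  u2 <- diphone_unit("bc", trajectory_matrix(matrix(0.4, 1, 3), 60),
                     "u2", c(9, 12))
  out <- gapless_concatenate(list(u1, u2))
  expect_equal(unname(unclass(out)[1, ]), c(0.1, 0.2, 0.3, 0.4, 0.4, 0.4))
  expect_equal(attr(out, "boundary_audit")$mismatch, 0)
})

test_that("zero gaps leave a plain concatenation untouched", {
  set.seed(73)
  traj <- trajectory_matrix(matrix(rnorm(2 * 20), 2, 20), 60)
  u1 <- diphone_unit("ab", traj_slice(traj, 1:10), "u", c(0, 10))
  u2 <- diphone_unit("bc", traj_slice(traj, 11:20), "u", c(10, 20))
  out <- gapless_concatenate(list(u1, u2))
  expect_equal(unclass(out), unclass(traj), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(attr(out, "boundary_audit")$contiguous)
})

test_that("every processed join is exact and second differences survive", {
  set.seed(74)
  for (trial in 1:100) {
    n <- sample(2:6, 1)
    units <- lapply(seq_len(n), function(s)
      random_unit(paste0("u", s), sprintf("src%d", sample(1:3, 1)),
                  sample(0:100, 1), sample(3:8, 1)))
    originals <- lapply(units, function(u) unclass(u$trajectory))
    out <- gapless_concatenate(units)
    audit <- attr(out, "boundary_audit")
    proc <- which(!audit$contiguous)
    if (length(proc))
      expect_lt(max(audit$mismatch[proc]), 1e-9)
    # within-unit second differences unchanged by the linear ramp: the
    # output segment of unit s is a contiguous run of its adjusted
    # trajectory, whose curvature equals the original's
    pos <- 1L
    for (s in seq_len(n)) {
      T_s <- ncol(originals[[s]])
      first_kept <- if (s > 1L && !audit$contiguous[s - 1L]) 2L else 1L
      len <- T_s - first_kept + 1L
      seg_out <- unclass(out)[, pos:(pos + len - 1L), drop = FALSE]
      pos <- pos + len
      if (len >= 3L) {
        d2_out <- t(diff(diff(t(seg_out))))
        d2_in <- t(diff(diff(t(
          originals[[s]][, first_kept:T_s, drop = FALSE]))))
        expect_lt(max(abs(d2_out - d2_in)), 1e-9)
      }
    }
  }
})

test_that("missing diphones fall back to second-phone units, then bridges", {
  set.seed(75)
  u_ab <- random_unit("ab", "u1", 0, 5)
  u_xb <- random_unit("xb", "u2", 0, 5)
  u_bc <- random_unit("bc", "u1", 5, 5)
  dict <- structure(list(ab = list(u_ab), xb = list(u_xb),
                         bc = list(u_bc)),
                    class = "diphone_dictionary")
  # target "zb" missing: falls back to any unit ending in b
  targets <- data.frame(label = c("zb", "bc"), duration = 0.1,
                        start = 0, end = 0.1)
  class(targets) <- c("diphone_targets", "data.frame")
  sel <- select_units(targets, dict)
  expect_true(sel[[1]]$label %in% c("ab", "xb"))
  # no unit ends in q: a linear 2-frame bridge is inserted with a warning
  targets2 <- data.frame(label = c("ab", "qq", "bc"), duration = 0.1,
                         start = 0, end = 0.1)
  class(targets2) <- c("diphone_targets", "data.frame")
  expect_warning(sel2 <- select_units(targets2, dict), "bridge")
  expect_equal(sel2[[2]]$source_utterance, "<bridge>")
  expect_equal(ncol(sel2[[2]]$trajectory), 2L)
  expect_equal(unclass(sel2[[2]]$trajectory)[, 1],
               unclass(sel2[[1]]$trajectory)[, 5])
})

test_that("full synthesis is continuous, clipped and error-propagating", {
  set.seed(76)
  entries <- lapply(1:6, function(i) {
    seg <- random_segmentation(6, seed = 760 + i,
                               utterance_id = sprintf("s%d", i))
    n_fr <- ceiling(seg$end[6] * 60 + 2)
    list(seg = seg,
         traj = trajectory_matrix(matrix(rnorm(2 * n_fr, sd = 2), 2), 60))
  })
  dict <- build_dictionary(entries)
  phones <- entries[[1]]$seg$label
  durs <- diff(c(0, entries[[1]]$seg$end))
  out <- suppressWarnings(synthesize_trajectories(phones, durs, dict))
  audit <- attr(out, "boundary_audit")
  if (any(!audit$contiguous))
    expect_lt(max(audit$mismatch[!audit$contiguous]), 1e-9)
  expect_true(all(unclass(out) >= -3 & unclass(out) <= 3))
  span <- diff(range(segmentation_midpoints(entries[[1]]$seg)))
  expect_lt(abs(ncol(out) / 60 - span), 2 / 60)
  expect_error(synthesize_trajectories(character(0), numeric(0), dict),
               "at least 2")
})

test_that("self-resynthesis reproduces the inverted trajectory", {
  truth <- fixture_truth()
  phones <- c("_", "w", "E", "l", "k", "@", "m", "_")
  durs <- rep(4 / 30, 8)   # midpoints land on the 60 Hz grid
  s <- simulate_sentence(truth, phones, durs, seed = 77, noise_sd = 0,
                         missing_rate = 0, head_motion_amplitude = c(0, 0))
  merged <- synchronize(s$ema, s$mocap)
  inv <- invert_recording(select_sensors(merged, truth$layout$face), truth,
                          smooth = FALSE)
  traj <- inv$raw_trajectories
  dict <- build_dictionary(list(list(seg = s$seg, traj = traj)))
  out <- synthesize_trajectories(phones, durs, dict)
  f <- floor(segmentation_midpoints(s$seg) * 60 + 1e-9)
  ref <- unclass(traj)[, (f[1] + 1):f[length(f)], drop = FALSE]
  expect_equal(dim(unclass(out)), dim(ref))
  expect_lt(sqrt(mean((unclass(out) - ref)^2)), 1e-6)
})
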