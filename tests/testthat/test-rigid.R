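# Rigid head-motion estimation: Euler conventions, Kabsch recovery,
# apply/remove round trips and the head-motion PCA model.

make_headset_series <- function(params_list, ref, center, rate = 60) {
  n <- length(params_list)
  pos <- array(0, c(n, nrow(ref), 3))
  for (i in seq_len(n))
    pos[i, , ] <- apply_rigid_pose(ref, params_list[[i]], center)
  sensor_series(pos, rate, rownames(ref))
}

ref_headset <- function() {
  m <- rbind(h1 = c(-45, 65, 20), h2 = c(45, 65, 20),
             h3 = c(-45, 85, -15), h4 = c(45, 85, -15))
  m
}

test_that("Euler conversion round-trips over the working range", {
  set.seed(3)
  for (i in 1:100) {
    ang <- runif(3, -80, 80)
    R <- euler_to_rotation(ang[1], ang[2], ang[3])
    expect_lt(max(abs(rotation_to_euler(R) - ang)), 1e-9)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
  }
})

test_that("identity motion is estimated as exactly zero", {
  ref <- ref_headset()
  ser <- make_headset_series(rep(list(numeric(6)), 10), ref, c(0, -110, -20))
  rig <- estimate_rigid_motion(ser, rownames(ref), reference_frame = ref)
  expect_lt(max(abs(rig$params)), 1e-9)
})

test_that("a known rotation + translation is recovered within 1e-6", {
  ref <- ref_headset()
  center <- c(0, -110, -20)
  truth <- c(5, 0, 0, 0, 0, 10)   # 5 mm in x, 10 degrees about z
  ser <- make_headset_series(list(numeric(6), truth), ref, center)
  rig <- estimate_rigid_motion(ser, rownames(ref), reference_frame = ref,
                               center = center)
  expect_lt(max(abs(rig$params[2, ] - truth)), 1e-6)
  set.seed(8)
  for (i in 1:25) {
    p <- c(runif(3, -10, 10), runif(3, -15, 15))
    ser <- make_headset_series(list(p), ref, center)
    rig <- estimate_rigid_motion(ser, rownames(ref), reference_frame = ref,
                                 center = center)
    expect_lt(max(abs(rig$params[1, ] - p)), 1e-6)
  }
})

test_that("remove then re-estimate yields identity, apply inverts remove", {
  ref <- ref_headset()
  center <- c(0, -110, -20)
  set.seed(9)
  params <- lapply(1:20, function(i) c(runif(3, -8, 8), runif(3, -12, 12)))
  ser <- make_headset_series(params, ref, center)
  rig <- estimate_rigid_motion(ser, rownames(ref), reference_frame = ref,
                               center = center)
  corrected <- remove_rigid_motion(ser, rig)
  # headset static in the head frame
  for (i in seq_len(20))
    expect_lt(max(abs(corrected$positions[i, , ] - ref)), 1e-9)
  rig2 <- estimate_rigid_motion(corrected, rownames(ref),
                                reference_frame = ref, center = center)
  expect_lt(max(abs(rig2$params)), 1e-9)
  # round trip apply(remove(x)) == x
  back <- apply_rigid_motion(corrected, rig)
  expect_lt(max(abs(back$positions - ser$positions)), 1e-9)
  # articulation (inter-sensor distances) preserved by removal
  d0 <- dist(ser$positions[5, , ])
  d1 <- dist(corrected$positions[5, , ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("the joint centre-of-rotation estimate matches the planted centre", {
  ref <- ref_headset()
  center <- c(3, -95, -12)
  set.seed(10)
  params <- lapply(1:40, function(i) c(0, 0, 0, runif(3, -15, 15)))
  ser <- make_headset_series(params, ref, center)
  rig <- estimate_rigid_motion(ser, rownames(ref), reference_frame = ref)
  expect_lt(max(abs(rig$center - center)), 1e-6)
  expect_lt(max(abs(rig$params[, 1:3])), 1e-6)
})

test_that("frames with too few rigid sensors are flagged and interpolated", {
  ref <- ref_headset()
  center <- c(0, -110, -20)
  params <- lapply(seq(0, 10, length.out = 11),
                   function(tx) c(tx, 0, 0, 0, 0, 0))
  ser <- make_headset_series(params, ref, center)
  ser$mask[6, 1:2] <- FALSE
  rig <- estimate_rigid_motion(ser, rownames(ref), reference_frame = ref,
                               center = center)
  expect_true(rig$flagged[6])
  expect_lt(abs(rig$params[6, 1] - 5), 1e-6)  # linear interpolation of Tx
})

test_that("head-motion PCA reports explained variance per component", {
  set.seed(11)
  # motion confined to Tx -> one component at 100 %
  p1 <- cbind(rnorm(50), 0, 0, 0, 0, 0)
  r1 <- rigid_motion(p1, (0:49) / 60, c(0, 0, 0))
  expect_warning(hm1 <- fit_head_motion_model(r1), "rank-deficient")
  expect_equal(hm1$explained[1], 100, tolerance = 1e-9)
  # two dominant components explain > 90 %
  base <- cbind(rnorm(500, sd = 5), rnorm(500, sd = 4),
                matrix(rnorm(500 * 4, sd = 0.3), 500, 4))
  r2 <- rigid_motion(base, (0:499) / 60, c(0, 0, 0))
  hm2 <- fit_head_motion_model(r2)
  expect_gt(sum(hm2$explained[1:2]), 90)
  expect_equal(ncol(hm2$loadings), 6L)
  # constant motion: degenerate, zero variance
  r3 <- rigid_motion(matrix(1, 10, 6), (0:9) / 60, c(0, 0, 0))
  expect_error(fit_head_motion_model(r3), "zero variance")
})
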