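# Synthetic-data generator: planted variance accounting, orthogonality,
# stream structure, determinism.

test_that("planted loadings are orthogonal and reproduce the profile exactly", {
  truth <- fixture_truth()
  L <- cbind(truth$loadings, truth$nuisance_loadings)
  G <- crossprod(L)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-9)
  expect_equal(sum(diag(G)), 100, tolerance = 1e-9)
  # direct variance accounting from the loadings matches the profile
  planted <- 100 * colSums(truth$loadings^2) / sum(diag(G))
  expect_lt(max(abs(planted - truth$variance_fractions)), 1e-12)
  # dominant loadings confined to the designated landmark subsets
  for (nm in c("tongue1", "tongue2", "lips2", "lips3", "jaw2", "eyebrows1")) {
    idx <- artic:::scheme_columns(truth$scheme$steps[[nm]], truth$coords)
    v <- truth$loadings[, nm]
    expect_gt(sum(v[idx]^2) / sum(v^2), 0.99)
  }
})

test_that("a single-parameter profile at 100 % gives a rank-1 model", {
  spec <- ground_truth_spec(variance_profile = c(jaw1 = 100), seed = 3)
  m <- make_ground_truth_model(spec)
  expect_null(m$nuisance_loadings)
  expect_equal(qr(m$loadings)$rank, 1L)
  expect_equal(sum(m$loadings^2), 100, tolerance = 1e-9)
})

test_that("profiles that cannot be absorbed are rejected", {
  expect_error(ground_truth_spec(variance_profile = c(jaw1 = 60, lips1 = 50)),
               "sum")
  expect_error(
    make_ground_truth_model(
      ground_truth_spec(variance_profile = c(jaw1 = 5, nosuch = 5))),
    "unknown parameters")
  # tiny profile over every group leaves more residual than the capped
  # nuisance directions can carry
  tiny <- c(jaw1 = 1, tongue1 = 1, tongue2 = 0.5, tongue3 = 0.5,
            tongue4 = 0.5, lips1 = 1, lips2 = 0.2, lips3 = 0.3,
            jaw2 = 0.3, eyebrows1 = 0.5)
  expect_error(
    make_ground_truth_model(ground_truth_spec(variance_profile = tiny)),
    "can absorb at most")
})

test_that("whitened frame sampling reproduces the planted profile numerically", {
  truth <- fixture_truth()
  X <- simulate_model_frames(truth, 2000, seed = 41)
  cv <- stats::cov(X)
  expect_equal(sum(diag(cv)), 100, tolerance = 1e-6)
  v1 <- truth$loadings[, "jaw1"]
  expect_equal(as.numeric(t(v1) %*% cv %*% v1) / sum(v1^2)^2 * sum(v1^2),
               sum(v1^2), tolerance = 1e-6)
})

test_that("a constant single-phone sentence sits at the projected posture", {
  truth <- fixture_truth()
  s <- simulate_sentence(truth, "O", 1, seed = 42, noise_sd = 0,
                         missing_rate = 0, head_motion_amplitude = c(0, 0))
  cb <- phone_codebook(truth)
  expected <- project_frame(truth, cb[, "O"])
  jaw1_cols <- coord_names("jaw_1")
  got <- s$mocap$positions[10, "jaw_1", ]
  expect_lt(max(abs(got - expected[jaw1_cols])), 1e-9)
  expect_lt(max(abs(unclass(s$truth$traj) - cb[, "O"])), 1e-9)
})

test_that("stream frame counts follow rate times duration", {
  truth <- fixture_truth()
  s <- simulate_sentence(truth, c("_", "b", "A:", "d", "@", "_"),
                         rep(1 / 3, 6), seed = 43)
  expect_equal(n_frames(s$mocap), 120L)
  expect_equal(n_frames(s$ema), 200L)
  expect_equal(s$mocap$rate, 60)
  expect_equal(s$ema$rate, 100)
  expect_equal(s$ema$times[1], s$mocap$times[1])
})

test_that("sentence simulation is bit-identical under a fixed seed", {
  truth <- fixture_truth()
  s1 <- simulate_sentence(truth, c("_", "m", "_"), c(0.3, 0.5, 0.3),
                          seed = 44)
  s2 <- simulate_sentence(truth, c("_", "m", "_"), c(0.3, 0.5, 0.3),
                          seed = 44)
  expect_identical(s1$ema$positions, s2$ema$positions)
  expect_identical(s1$mocap$positions, s2$mocap$positions)
  expect_identical(s1$mocap$mask, s2$mocap$mask)
  s3 <- simulate_sentence(truth, c("_", "m", "_"), c(0.3, 0.5, 0.3),
                          seed = 45)
  expect_false(identical(s1$ema$positions, s3$ema$positions))
})

test_that("unknown phone labels are reported by name", {
  truth <- fixture_truth()
  expect_error(simulate_sentence(truth, c("_", "xx"), c(0.3, 0.3)),
               "xx")
})

test_that("corpus generation writes a re-readable manifest deterministically", {
  truth <- fixture_truth()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  c1 <- simulate_corpus(truth, 2, duration = 2, seed = 46, out_dir = dir1)
  c2 <- simulate_corpus(truth, 2, duration = 2, seed = 46, out_dir = dir2)
  expect_equal(nrow(c1$manifest), 8L)
  expect_identical(c1$manifest$md5, c2$manifest$md5)
  seg <- read_segmentation(file.path(dir1, "sent0001.lab"), "lab")
  expect_identical(seg$label, c1$sentences[[1]]$seg$label)
  back <- read_trajectory(file.path(dir1, "sent0001_traj.csv"))
  expect_lt(max(abs(unclass(back) - unclass(c1$sentences[[1]]$truth$traj))),
            1e-9)
})

test_that("missing samples appear at roughly the requested rate", {
  truth <- fixture_truth()
  s <- simulate_sentence(truth, c("_", "A:", "_"), c(1, 3, 1), seed = 47,
                         missing_rate = 0.1)
  rate_obs <- mean(!s$mocap$mask)
  expect_gt(rate_obs, 0.06)
  expect_lt(rate_obs, 0.14)
})
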