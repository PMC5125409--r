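# Avatar retargeting: key-frame normalization, bounded mixture fitting,
# posture database and the 5-parameter avatar tongue model.

test_that("face key-frame normalization follows the closed form", {
  V <- 8
  neutral <- matrix(0, V, 3)
  unit_z <- neutral; unit_z[, 3] <- 1       # unit displacement everywhere
  ks <- keyframe_set(neutral, list(jaw1 = unit_z))
  par <- face_keyframes_to_params(ks)
  # RMS per-vertex displacement is 1, so activation 3 moves 3 units in z
  pose3 <- avatar_face_pose(par, c(jaw1 = 3))
  expect_lt(max(abs(pose3[, 3] - 3)), 1e-12)
  expect_lt(max(abs(pose3[, 1:2])), 1e-12)
  # activation 0 is exactly the neutral mesh
  expect_equal(avatar_face_pose(par, c(jaw1 = 0)), neutral)
  expect_equal(par$activation_range, c(0, 3))
})

test_that("four key frames yield four parameters and none is jaw2", {
  set.seed(50)
  neutral <- matrix(rnorm(30), 10, 3)
  kfs <- lapply(1:4, function(i) neutral + matrix(rnorm(30, sd = 2), 10, 3))
  names(kfs) <- c("jaw1", "lips1", "lips2", "lips3")
  par <- face_keyframes_to_params(keyframe_set(neutral, kfs))
  expect_length(par$parameter_names, 4L)
  expect_false("jaw2" %in% par$parameter_names)
})

test_that("a key frame identical to neutral is a zero-variance error", {
  neutral <- matrix(rnorm(15), 5, 3)
  expect_error(face_keyframes_to_params(
    keyframe_set(neutral, list(k = neutral))), "identical")
})

test_that("mixture fitting recovers a one-hot key-frame target", {
  ks <- toy_keyframes(seed = 51)
  for (j in seq_along(ks$keyframes)) {
    ema <- ks$keyframes[[j]][ks$correspondence, ]
    rownames(ema) <- names(ks$correspondence)
    fit <- fit_tongue_mixture(ema, ks)
    expected <- numeric(length(ks$keyframes)); expected[j] <- 1
    expect_lt(max(abs(fit$weights - expected)), 1e-6)
    expect_lt(max(fit$residual_per_sensor), 1e-6)
  }
})

test_that("a zero target fits with vanishing sensor residual", {
  ks <- toy_keyframes(seed = 52)
  ema <- matrix(0, 3, 3, dimnames = list(c("TT", "TB", "TD"), NULL))
  fit <- fit_tongue_mixture(ema, ks)
  expect_lt(max(abs(fit$mesh[ks$correspondence, ])), 1e-8)
})

test_that("unreachable targets activate at least one weight bound", {
  ks <- toy_keyframes(seed = 53)
  ema <- ks$keyframes[[1]][ks$correspondence, ] * 100
  rownames(ema) <- names(ks$correspondence)
  fit <- fit_tongue_mixture(ema, ks)
  expect_true(any(abs(abs(fit$weights) - 10) < 1e-8))
  expect_gt(fit$residual, 0)
})

test_that("bounded mixture weights match the exhaustive oracle on toys", {
  set.seed(54)
  worst <- 0
  for (i in 1:30) {
    neutral <- matrix(rnorm(9), 3, 3)
    kfs <- lapply(1:3, function(k) matrix(rnorm(9, sd = 2), 3, 3))
    names(kfs) <- paste0("k", 1:3)
    ks <- keyframe_set(neutral, kfs, c(TT = 1L, TB = 2L, TD = 3L))
    ema <- matrix(rnorm(9, sd = 6), 3, 3,
                  dimnames = list(c("TT", "TB", "TD"), NULL))
    fit <- fit_tongue_mixture(ema, ks, bounds = c(-2, 2))
    A <- vapply(kfs, function(k) as.vector(t(k)), numeric(9))
    worst <- max(worst,
                 max(abs(fit$weights -
                           bvls_oracle(A, as.vector(t(ema)), -2, 2))))
  }
  expect_lt(worst, 1e-7)
})

test_that("posture databases fit planted in-bounds mixtures exactly", {
  ks <- toy_keyframes(seed = 55, n_key = 3, n_vert = 10)
  set.seed(56)
  W <- matrix(runif(3 * 20, -2, 2), 20, 3)
  A <- vapply(ks$keyframes,
              function(k) as.vector(t(k[ks$correspondence, ])), numeric(9))
  postures <- W %*% t(A)
  colnames(postures) <- coord_names(names(ks$correspondence))
  q <- structure(list(coords = postures, index = 1:20, min_dist = 0),
                 class = "quantized_frames")
  db <- build_tongue_posture_db(q, ks)
  expect_lt(db$summary[["mean"]], 1e-6)
  expect_lt(max(abs(db$weights - W)), 1e-5)
  # empty database passes through
  q0 <- structure(list(coords = postures[0, , drop = FALSE],
                       index = integer(0), min_dist = 0),
                  class = "quantized_frames")
  expect_equal(nrow(build_tongue_posture_db(q0, ks)$meshes), 0L)
})

test_that("the avatar tongue model recovers a planted 5-parameter structure", {
  # quantized EMA frames from the planted speaker model (tongue + jaw)
  truth <- fixture_truth()
  X <- simulate_model_frames(truth, 400, seed = 57)
  keep <- coord_names(c("jaw_1", "jaw_2", "jaw_3", "TT", "TB", "TD"))
  q <- structure(list(coords = X[, keep], index = seq_len(nrow(X)),
                      min_dist = 0), class = "quantized_frames")
  # mesh vertices as noiseless linear images of the tongue sensors
  set.seed(58)
  V <- 50
  B <- matrix(rnorm(3 * V * 9, sd = 0.4), 3 * V, 9)
  meshes <- q$coords[, coord_names(c("TT", "TB", "TD"))] %*% t(B)
  colnames(meshes) <- coord_names(paste0("vtx_", 1:V))
  db <- structure(list(meshes = meshes,
                       weights = matrix(0, nrow(X), 0),
                       residuals = matrix(0, nrow(X), 3),
                       summary = c(mean = 0, sd = 0),
                       ema_coords = coord_names(c("TT", "TB", "TD"))),
                  class = "tongue_posture_db")
  avatar <- fit_avatar_tongue_model(db, q)
  expect_equal(avatar$parameter_names,
               c("jaw1", "tongue1", "tongue2", "tongue3", "tongue4"))
  # parameters drive all 50 mesh vertices
  mesh_rows <- grep("^vtx_", avatar$coords)
  expect_length(mesh_rows, 3L * V)
  expect_gt(sum(abs(avatar$loadings[mesh_rows, "tongue1"])), 0)
  # alpha = 0 projects to the mean tongue mesh
  mu <- predict(avatar, numeric(5))
  expect_lt(max(abs(mu[mesh_rows] - colMeans(meshes))), 1e-9)
})

test_that("sign alignment flips chosen loadings and is an involution", {
  truth <- fixture_truth()
  avatar <- truth
  out <- align_parameter_signs(truth, avatar, c(jaw1 = -1))
  expect_equal(out$loadings[, "jaw1"], -avatar$loadings[, "jaw1"])
  expect_equal(out$loadings[, "lips1"], avatar$loadings[, "lips1"])
  twice <- align_parameter_signs(truth, out, c(jaw1 = -1))
  expect_equal(twice$loadings, avatar$loadings)
  noflip <- align_parameter_signs(truth, avatar,
                                  stats::setNames(rep(1, 10),
                                                  truth$parameter_names))
  expect_equal(noflip$loadings, avatar$loadings)
  expect_error(align_parameter_signs(truth, avatar, c(bogus = 1)), "bogus")
})
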