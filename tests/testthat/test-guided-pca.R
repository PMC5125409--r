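# Guided PCA: subset extraction, variance accounting, planted-truth
# recovery and the plain-PCA equivalence oracle.

test_that("data varying only in jaw coordinates loads entirely on jaw1", {
  truth <- fixture_truth()
  set.seed(20)
  jaw_cols <- grep("^jaw_", truth$coords)
  n <- 400
  # rank-1 jaw articulation plus numerically negligible jitter elsewhere
  # (a strictly zero-variance subset is a specified error path)
  X <- matrix(rnorm(n * length(truth$coords), sd = 1e-7), n,
              length(truth$coords), dimnames = list(NULL, truth$coords))
  dir <- rnorm(length(jaw_cols))
  X[, jaw_cols] <- X[, jaw_cols] + outer(rnorm(n, sd = 2), dir)
  X <- sweep(X, 2, truth$mean, `+`)
  fit <- fit_guided_pca(X, truth$scheme)
  expect_gt(fit$variance_fractions[["jaw1"]], 99)
  others <- fit$variance_fractions[setdiff(names(fit$variance_fractions),
                                           c("jaw1", "jaw2"))]
  expect_lt(max(others), 1e-8)
})

test_that("a planted orthogonal model is recovered exactly from whitened frames", {
  truth <- fixture_truth()
  X <- simulate_model_frames(truth, 3000, seed = 23)
  fit <- fit_guided_pca(prune_frames(X, 0.5), truth$scheme)
  expect_lt(max(abs(fit$variance_fractions - truth$variance_fractions)),
            1e-6)
  # principal angle between planted and recovered loading directions
  for (k in seq_along(truth$parameter_names)) {
    a <- truth$loadings[, k]; b <- fit$loadings[, k]
    cosang <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
    expect_lt(acos(min(1, cosang)), 1e-6)
  }
  # loading scale: planted mm-per-SD norms are reproduced
  expect_lt(max(abs(sqrt(colSums(fit$loadings^2)) -
                      sqrt(colSums(truth$loadings^2)))), 1e-6)
})

test_that("variance fractions are non-negative and sum below 100 on any input", {
  set.seed(24)
  for (i in 1:5) {
    X <- matrix(rnorm(300 * 9), 300, 9,
                dimnames = list(NULL, coord_names(c("TT", "TB", "TD"))))
    sch <- extraction_scheme(list(t1 = c("TB", "TD"), t2 = "TT",
                                  t3 = c("TB", "TD")))
    fit <- fit_guided_pca(X, sch)
    expect_true(all(fit$variance_fractions >= 0))
    expect_lte(sum(fit$variance_fractions), 100 + 1e-9)
  }
})

test_that("residual after extraction is orthogonal to every score", {
  truth <- fixture_truth()
  X <- simulate_model_frames(truth, 1500, noise_sd = 1, whiten = FALSE,
                             seed = 25)
  # re-run the extraction by hand to access scores and residual
  scheme <- truth$scheme
  R <- sweep(X, 2, colMeans(X))
  n <- nrow(R)
  scores <- NULL
  for (k in seq_along(scheme$steps)) {
    idx <- artic:::scheme_columns(scheme$steps[[k]], colnames(X))
    u <- svd(R[, idx, drop = FALSE], nu = 0, nv = 1)$v[, 1]
    s <- as.vector(R[, idx, drop = FALSE] %*% u)
    s <- s / sqrt(sum(s^2) / (n - 1))
    v <- as.vector(crossprod(R, s)) / (n - 1)
    R <- R - tcrossprod(s, v)
    scores <- cbind(scores, s)
  }
  expect_lt(max(abs(crossprod(scores, R))) / n, 1e-9)
})

test_that("a single-subset scheme reproduces the plain PCA first component", {
  set.seed(26)
  X <- matrix(rnorm(500 * 6), 500, 6) %*% diag(c(4, 3, 2, 1, 1, 1))
  colnames(X) <- coord_names(c("TB", "TD"))
  fit <- fit_guided_pca(X, extraction_scheme(list(t1 = c("TB", "TD"))))
  # brute-force eigendecomposition oracle
  C <- stats::cov(X)
  eig <- eigen(C, symmetric = TRUE)
  frac_oracle <- 100 * eig$values[1] / sum(eig$values)
  expect_equal(unname(fit$variance_fractions[1]), frac_oracle,
               tolerance = 1e-9)
  dir_fit <- fit$loadings[, 1] / sqrt(sum(fit$loadings[, 1]^2))
  cosang <- abs(sum(dir_fit * eig$vectors[, 1]))
  expect_lt(acos(min(1, cosang)), 1e-9)
})

test_that("fitting is deterministic and order-invariant in the frames", {
  truth <- fixture_truth()
  X <- simulate_model_frames(truth, 800, seed = 27)
  f1 <- fit_guided_pca(X, truth$scheme)
  f2 <- fit_guided_pca(X, truth$scheme)
  expect_identical(f1$loadings, f2$loadings)
  perm <- sample(nrow(X))
  f3 <- fit_guided_pca(X[perm, ], truth$scheme)
  expect_lt(max(abs(f3$variance_fractions - f1$variance_fractions)), 1e-9)
})

test_that("variance_report reproduces stored fractions on the fitting data", {
  truth <- fixture_truth()
  X <- simulate_model_frames(truth, 1000, seed = 28)
  pr <- prune_frames(X, 0.5)
  fit <- fit_guided_pca(pr, truth$scheme)
  rep <- variance_report(fit, pr)
  expect_equal(rep$percent, unname(fit$variance_fractions),
               tolerance = 1e-9)
  expect_equal(rep$parameter, fit$parameter_names)
})

test_that("projection is affine-linear and recovers the mean at alpha = 0", {
  truth <- fixture_truth()
  expect_equal(project_frame(truth, numeric(10)), truth$mean)
  set.seed(29)
  a1 <- rnorm(10); a2 <- rnorm(10)
  lhs <- project_frame(truth, a1 + a2) - truth$mean
  rhs <- (project_frame(truth, a1) - truth$mean) +
    (project_frame(truth, a2) - truth$mean)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  # opposite extremes are mirror images about the mean
  e1 <- project_frame(truth, c(3, rep(0, 9)))
  e2 <- project_frame(truth, c(-3, rep(0, 9)))
  expect_lt(max(abs((e1 + e2) / 2 - truth$mean)), 1e-9)
})

test_that("degenerate inputs fail with informative errors", {
  truth <- fixture_truth()
  X <- simulate_model_frames(truth, 100, seed = 30)
  expect_error(fit_guided_pca(X[1:10, ], truth$scheme), "at least")
  Xz <- X; Xz[, grep("^brow", colnames(X))] <-
    rep(colMeans(Xz[, grep("^brow", colnames(X))]), each = nrow(Xz))
  expect_error(fit_guided_pca(Xz, truth$scheme), "eyebrows1")
  expect_error(predict(truth, numeric(3)), "expected 10")
})
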