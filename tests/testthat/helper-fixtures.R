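# Shared fixtures: small planted models, random segmentations, toy
# key-frame sets, and independent oracles used across test files.

# small planted model cached across tests (construction is deterministic)
fixture_truth <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache) || cache$spec$seed != seed)
      cache <<- make_ground_truth_model(ground_truth_spec(seed = seed))
    cache
  }
})

random_segmentation <- function(n, seed, utterance_id = "rand") {
  with_seed_local(seed, {
    labs <- sample(sampa_inventory(), n, replace = TRUE)
    ends <- cumsum(runif(n, 0.05, 0.4))
  })
  phone_segmentation(labs, ends, utterance_id)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eval.parent(substitute(code))
}

# exhaustive active-set oracle for box-constrained least squares (tiny n)
bvls_oracle <- function(A, b, lo, hi) {
  n <- ncol(A)
  best <- NULL; bestf <- Inf
  states <- expand.grid(rep(list(0:2), n))
  for (r in seq_len(nrow(states))) {
    st <- unlist(states[r, ])
    free <- which(st == 0)
    x <- ifelse(st == 1, lo, hi)
    if (length(free)) {
      rhs <- if (length(free) == n) crossprod(A, b)
      else crossprod(A[, free, drop = FALSE],
                     b - A[, -free, drop = FALSE] %*% x[-free])
      sol <- tryCatch(solve(crossprod(A[, free, drop = FALSE]) +
                              diag(1e-12, length(free)), rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[free] <- sol
    }
    if (any(x < lo - 1e-9 | x > hi + 1e-9)) next
    f <- sum((A %*% x - b)^2)
    if (f < bestf - 1e-12) { bestf <- f; best <- x }
  }
  best
}

# brute-force path search over a unit-selection trellis
exhaustive_selection <- function(slots) {
  combs <- expand.grid(lapply(slots, seq_along))
  bestc <- Inf; best <- NULL
  for (r in seq_len(nrow(combs))) {
    us <- lapply(seq_along(slots), function(s) slots[[s]][[combs[r, s]]])
    cost <- 0
    for (s in seq_len(length(us) - 1L))
      cost <- cost + artic:::boundary_cost(us[[s]], us[[s + 1L]])
    if (cost < bestc - 1e-12) { bestc <- cost; best <- us }
  }
  list(cost = bestc, units = best)
}

random_unit <- function(label, utterance, start, n_frames, n_par = 3,
                        rate = 60) {
  vals <- matrix(stats::rnorm(n_par * n_frames), n_par, n_frames,
                 dimnames = list(paste0("p", seq_len(n_par)), NULL))
  diphone_unit(label, trajectory_matrix(vals, rate), utterance,
               c(start, start + n_frames))
}

# amplitude of a sinusoid at a known frequency, by least squares on the
# central portion of the signal (edge-transient free)
probe_amplitude <- function(x, freq, rate, trim = 0.25) {
  n <- length(x)
  keep <- seq(ceiling(n * trim), floor(n * (1 - trim)))
  t <- (keep - 1) / rate
  basis <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- stats::lm.fit(basis, x[keep] - mean(x[keep]))$coefficients
  sqrt(sum(cf^2))
}

# tiny toy key-frame set: 6-vertex mesh, 3 key frames, TT/TB/TD on
# vertices 1..3
toy_keyframes <- function(seed = 1, n_key = 3, n_vert = 6) {
  with_seed_local(seed, {
    neutral <- matrix(stats::rnorm(n_vert * 3, sd = 5), n_vert, 3)
    kfs <- lapply(seq_len(n_key), function(i)
      neutral + matrix(stats::rnorm(n_vert * 3, sd = 3), n_vert, 3))
  })
  names(kfs) <- paste0("key", seq_len(n_key))
  keyframe_set(neutral, kfs,
               correspondence = c(TT = 1L, TB = 2L, TD = 3L))
}
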