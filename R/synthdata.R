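# Ground-truth simulation: planted articulatory models and multimodal
# corpora (EMA at 100 Hz + mocap at 60 Hz + segmentations) with known
# parameters, so every downstream stage can be checked against a
# recoverable truth.
#
# The planted model is built so that each articulatory parameter's share of
# the total variance equals its profile entry exactly: loading vectors are
# mutually orthogonal, scores have unit variance, and the variance not
# accounted for by the named parameters is carried by additional orthogonal
# "nuisance" directions confined to the landmark groups, each weak enough
# never to win a subset PCA step.

# Percent-of-global-variance profile for the default 10-parameter model.
default_variance_profile <- function() {
  c(jaw1 = 13.40, tongue1 = 13.17, tongue2 = 4.83, tongue3 = 5.13,
    tongue4 = 5.69, lips1 = 10.06, lips2 = 0.93, lips3 = 2.66,
    jaw2 = 2.04, eyebrows1 = 4.23)
}

#' Specification of a simulated recording setup
#'
#' Collects the generator's study conditions: sensor layout counts, the
#' per-parameter variance profile of the planted articulatory model,
#' sensor noise, rigid head-motion amplitude and the missing-sample rate.
#'
#' @param variance_profile named numeric vector: percentage of global
#'   variance per articulatory parameter, in extraction order (default:
#'   the 10-parameter face-and-tongue profile).
#' @param noise_sd i.i.d. Gaussian sensor noise SD in mm (default 0.5).
#' @param head_motion_amplitude length-2 vector: peak translation (mm) and
#'   rotation (degrees) of the slow sinusoidal head motion (default
#'   `c(8, 4)`).
#' @param missing_rate probability that a sensor sample is missing
#'   (default 0.005).
#' @param seed integer seed for the planted model construction.
#' @param n_jaw,n_lower_lip,n_upper_lip,n_eyebrows,n_headset sensor counts
#'   per group (defaults 3, 4, 4, 6, 4; the tongue always carries TT, TB,
#'   TD and the EMA reference sensors are nasion and both tragi).
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(variance_profile = default_variance_profile(),
                              noise_sd = 0.5,
                              head_motion_amplitude = c(8, 4),
                              missing_rate = 0.005,
                              seed = 1L,
                              n_jaw = 3L, n_lower_lip = 4L,
                              n_upper_lip = 4L, n_eyebrows = 6L,
                              n_headset = 4L) {
  if (is.null(names(variance_profile)) || any(!nzchar(names(variance_profile))))
    abort_artic("variance_profile must be a named vector")
  if (any(variance_profile <= 0))
    abort_artic("variance fractions must be positive")
  if (sum(variance_profile) > 100 + 1e-9)
    abort_artic("variance fractions sum to %.2f%% > 100%%",
                sum(variance_profile))
  check_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) abort_artic("'noise_sd' must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    abort_artic("'missing_rate' must be in [0, 1)")
  structure(list(variance_profile = variance_profile, noise_sd = noise_sd,
                 head_motion_amplitude = head_motion_amplitude,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 n_jaw = n_jaw, n_lower_lip = n_lower_lip,
                 n_upper_lip = n_upper_lip, n_eyebrows = n_eyebrows,
                 n_headset = n_headset),
            class = "ground_truth_spec")
}

#' Nominal sensor layout in the head frame (mm)
#' @noRd
sensor_layout <- function(spec) {
  ring <- function(n, x0, x1, y, z) {
    x <- if (n == 1L) (x0 + x1) / 2 else seq(x0, x1, length.out = n)
    cbind(x, rep(y, n), rep(z, n))
  }
  jaw <- ring(spec$n_jaw, -20, 20, -65, 85)
  lipL <- ring(spec$n_lower_lip, -18, 18, -35, 100)
  lipU <- ring(spec$n_upper_lip, -18, 18, -22, 100)
  brow <- ring(spec$n_eyebrows, -35, 35, 40, 95)
  tongue <- rbind(TT = c(0, -45, 70), TB = c(0, -50, 45), TD = c(0, -55, 25))
  head <- rbind(c(-45, 65, 20), c(45, 65, 20), c(-45, 85, -15), c(45, 85, -15))
  head <- head[seq_len(spec$n_headset), , drop = FALSE]
  ref <- rbind(nasion = c(0, 20, 100), tragusL = c(-72, -10, 0),
               tragusR = c(72, -10, 0))
  pos <- rbind(jaw, lipL, lipU, brow, tongue, head, ref)
  names <- c(paste0("jaw_", seq_len(spec$n_jaw)),
             paste0("lipL_", seq_len(spec$n_lower_lip)),
             paste0("lipU_", seq_len(spec$n_upper_lip)),
             paste0("brow_", seq_len(spec$n_eyebrows)),
             "TT", "TB", "TD",
             paste0("head_", seq_len(spec$n_headset)),
             "nasion", "tragusL", "tragusR")
  rownames(pos) <- names
  list(positions = pos,
       face = names[seq_len(spec$n_jaw + spec$n_lower_lip +
                              spec$n_upper_lip + spec$n_eyebrows + 3L)],
       mocap = c(names[seq_len(spec$n_jaw + spec$n_lower_lip +
                                 spec$n_upper_lip + spec$n_eyebrows)],
                 paste0("head_", seq_len(spec$n_headset))),
       ema = c("TT", "TB", "TD", "nasion", "tragusL", "tragusR"),
       rigid = c(paste0("head_", seq_len(spec$n_headset)),
                 "nasion", "tragusL", "tragusR"),
       jaw = paste0("jaw_", seq_len(spec$n_jaw)),
       lower_lip = paste0("lipL_", seq_len(spec$n_lower_lip)),
       upper_lip = paste0("lipU_", seq_len(spec$n_upper_lip)),
       eyebrows = paste0("brow_", seq_len(spec$n_eyebrows)),
       neck_center = c(0, -110, -20))
}

#' Random orthonormal columns within a coordinate block
#' @noRd
ortho_cols <- function(d, k) {
  qr.Q(qr(matrix(stats::rnorm(d * max(k, 1L)), d, max(k, 1L))))[, seq_len(k),
                                                                drop = FALSE]
}

embed_cols <- function(D, idx, Q) {
  out <- matrix(0, D, ncol(Q))
  out[idx, ] <- Q
  out
}

#' Build a planted ground-truth articulatory model
#'
#' Constructs an articulatory model whose guided-PCA decomposition is known
#' exactly: orthogonal loading vectors whose squared norms equal the
#' requested percentages of a total variance of 100 mm^2, each dominant on
#' its designated landmark subset, plus orthogonal nuisance directions
#' carrying the remaining variance.  Two physiological couplings are
#' planted deliberately: jaw opening spills onto the tongue (the tongue is
#' carried by the jaw), and -- when the tongue-tip horizontal parameter
#' outweighs the vertical one -- part of its variance is carried by the
#' tongue body so that subset extraction order is preserved.
#'
#' @param spec a [ground_truth_spec()].
#' @return An object of class `c("ground_truth_model", "artmodel")`; the
#'   extra fields `nuisance_loadings`, `layout` and `codebook` drive
#'   simulation.
#' @export
make_ground_truth_model <- function(spec = ground_truth_spec()) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  profile <- spec$variance_profile
  lay <- sensor_layout(spec)
  coords <- coord_names(lay$face)
  D <- length(coords)
  mu <- as.vector(t(lay$positions[lay$face, ]))
  names(mu) <- coords
  cidx <- function(sensors) match(coord_names(sensors), coords)
  grp <- list(jaw = cidx(lay$jaw),
              tbtd = cidx(c("TB", "TD")),
              tt = cidx("TT"),
              lipL = cidx(lay$lower_lip),
              lipU = cidx(lay$upper_lip),
              brow = cidx(lay$eyebrows))
  full <- c(jaw1 = "jaw", tongue1 = "tbtd", tongue2 = "tbtd",
            tongue3 = "tt", tongue4 = "tt", lips1 = "lips",
            lips2 = "lipL", lips3 = "lipU", jaw2 = "jaw",
            eyebrows1 = "brow")
  if (!all(names(profile) %in% names(full)))
    abort_artic("unknown parameters in variance profile: %s",
                paste(setdiff(names(profile), names(full)), collapse = ", "))
  with_seed(spec$seed, {
    qjaw <- ortho_cols(length(grp$jaw), length(grp$jaw))
    qtb <- ortho_cols(length(grp$tbtd), length(grp$tbtd))
    qtt <- ortho_cols(length(grp$tt), length(grp$tt))
    qlL <- ortho_cols(length(grp$lipL), length(grp$lipL))
    qlU <- ortho_cols(length(grp$lipU), length(grp$lipU))
    qbr <- ortho_cols(length(grp$brow), length(grp$brow))
    lips_idx <- c(grp$lipL, grp$lipU)
    raw <- stats::rnorm(length(lips_idx))
    codebook_seed <- sample.int(.Machine$integer.max, 1L)
  })
  # lip rounding direction: spans both lips, orthogonal to the within-lip
  # directions reserved for lips2/lips3
  l2_dir <- embed_cols(length(lips_idx), seq_along(grp$lipL),
                       qlL[, 1L, drop = FALSE])
  l3_dir <- embed_cols(length(lips_idx),
                       length(grp$lipL) + seq_along(grp$lipU),
                       qlU[, 1L, drop = FALSE])
  l1_dir <- raw - l2_dir %*% crossprod(l2_dir, raw) -
    l3_dir %*% crossprod(l3_dir, raw)
  l1_dir <- l1_dir / sqrt(sum(l1_dir^2))

  loadings <- matrix(0, D, length(profile),
                     dimnames = list(coords, names(profile)))
  add_dir <- function(idx, q) embed_cols(D, idx, q)
  # jaw opening: 70% of its variance on the jaw sensors, 20% on the tongue
  # body, 10% on the tongue tip ("the tongue is carried by the jaw")
  if ("jaw1" %in% names(profile)) {
    v <- profile[["jaw1"]]
    loadings[, "jaw1"] <-
      sqrt(0.70 * v) * add_dir(grp$jaw, qjaw[, 1L, drop = FALSE]) +
      sqrt(0.20 * v) * add_dir(grp$tbtd, qtb[, 3L, drop = FALSE]) +
      sqrt(0.10 * v) * add_dir(grp$tt, qtt[, 3L, drop = FALSE])
  }
  if ("tongue1" %in% names(profile))
    loadings[, "tongue1"] <- sqrt(profile[["tongue1"]]) *
      add_dir(grp$tbtd, qtb[, 1L, drop = FALSE])
  if ("tongue2" %in% names(profile))
    loadings[, "tongue2"] <- sqrt(profile[["tongue2"]]) *
      add_dir(grp$tbtd, qtb[, 2L, drop = FALSE])
  if ("tongue3" %in% names(profile))
    loadings[, "tongue3"] <- sqrt(profile[["tongue3"]]) *
      add_dir(grp$tt, qtt[, 1L, drop = FALSE])
  if ("tongue4" %in% names(profile)) {
    v4 <- profile[["tongue4"]]
    v3 <- if ("tongue3" %in% names(profile)) profile[["tongue3"]] else Inf
    tt_part <- min(v4, 0.85 * v3)
    loadings[, "tongue4"] <-
      sqrt(tt_part) * add_dir(grp$tt, qtt[, 2L, drop = FALSE]) +
      sqrt(v4 - tt_part) * add_dir(grp$tbtd, qtb[, 4L, drop = FALSE])
  }
  if ("lips1" %in% names(profile))
    loadings[, "lips1"] <- sqrt(profile[["lips1"]]) *
      add_dir(lips_idx, l1_dir)
  if ("lips2" %in% names(profile))
    loadings[, "lips2"] <- sqrt(profile[["lips2"]]) *
      add_dir(grp$lipL, qlL[, 1L, drop = FALSE])
  if ("lips3" %in% names(profile))
    loadings[, "lips3"] <- sqrt(profile[["lips3"]]) *
      add_dir(grp$lipU, qlU[, 1L, drop = FALSE])
  if ("jaw2" %in% names(profile))
    loadings[, "jaw2"] <- sqrt(profile[["jaw2"]]) *
      add_dir(grp$jaw, qjaw[, 2L, drop = FALSE])
  if ("eyebrows1" %in% names(profile))
    loadings[, "eyebrows1"] <- sqrt(profile[["eyebrows1"]]) *
      add_dir(grp$brow, qbr[, 1L, drop = FALSE])

  # nuisance directions: remaining variance, confined to the groups, each
  # capped below the weakest parameter extracted from that group
  remaining <- 100 - sum(profile)
  pv <- function(nm) if (nm %in% names(profile)) profile[[nm]] else Inf
  nuis_space <- list(
    jaw = list(idx = grp$jaw, q = qjaw[, -(1:2), drop = FALSE],
               cap = 0.7 * min(pv("jaw1"), pv("jaw2"))),
    tbtd = list(idx = grp$tbtd, q = qtb[, -c(1:4), drop = FALSE],
                cap = 0.7 * min(pv("tongue1"), pv("tongue2"))),
    lipL = list(idx = grp$lipL,
                q = {
                  # orthogonal to lips2 and to lips1's lower-lip part
                  base <- cbind(qlL[, 1L], l1_dir[seq_along(grp$lipL)])
                  rest <- qlL[, -1L, drop = FALSE]
                  rest <- rest - base %*% solve(crossprod(base) +
                                                  diag(1e-12, 2L),
                                                crossprod(base, rest))
                  qr.Q(qr(rest))[, seq_len(length(grp$lipL) - 2L),
                                 drop = FALSE]
                },
                cap = 0.7 * min(pv("lips1"), pv("lips2"))),
    lipU = list(idx = grp$lipU,
                q = {
                  base <- cbind(qlU[, 1L],
                                l1_dir[length(grp$lipL) + seq_along(grp$lipU)])
                  rest <- qlU[, -1L, drop = FALSE]
                  rest <- rest - base %*% solve(crossprod(base) +
                                                  diag(1e-12, 2L),
                                                crossprod(base, rest))
                  qr.Q(qr(rest))[, seq_len(length(grp$lipU) - 2L),
                                 drop = FALSE]
                },
                cap = 0.7 * min(pv("lips1"), pv("lips3"))),
    brow = list(idx = grp$brow, q = qbr[, -1L, drop = FALSE],
                cap = 0.7 * pv("eyebrows1")))
  nuis <- NULL
  if (remaining > 1e-12) {
    # groups from which no parameter is extracted impose no cap
    weights <- vapply(nuis_space, function(s)
      if (is.finite(s$cap)) s$cap else remaining, 0)
    capacity <- sum(weights * vapply(nuis_space, function(s) ncol(s$q), 0L))
    if (remaining > capacity)
      abort_artic(paste0("variance profile leaves %.1f%% residual variance ",
                         "but the landmark groups can absorb at most %.1f%%"),
                  remaining, capacity)
    lambda <- remaining / capacity
    pieces <- Map(function(s, w) {
      if (ncol(s$q) == 0L) return(NULL)
      embed_cols(D, s$idx, s$q) * sqrt(lambda * w)
    }, nuis_space, weights)
    nuis <- do.call(cbind, pieces[!vapply(pieces, is.null, TRUE)])
  }
  total <- sum(loadings^2) + sum(nuis^2)
  model <- new_artmodel(mu, loadings, names(profile),
                        variance_fractions = profile,
                        total_variance = total,
                        scheme = default_extraction_scheme(
                          jaw = lay$jaw, lower_lip = lay$lower_lip,
                          upper_lip = lay$upper_lip, eyebrows = lay$eyebrows),
                        coords = coords)
  model$nuisance_loadings <- nuis
  model$layout <- lay
  model$codebook_seed <- codebook_seed
  model$spec <- spec
  class(model) <- c("ground_truth_model", "artmodel")
  model
}

#' Sample frames from a planted model
#'
#' Draws unit-variance scores for every parameter (and nuisance direction)
#' and projects them through the planted loadings.  By default the score
#' matrix is empirically whitened -- centred, decorrelated and scaled to
#' exactly unit sample variance -- so the sample variance accounting of the
#' generated frames matches the planted profile by construction, not just
#' in expectation.
#'
#' @param model a [make_ground_truth_model()] result.
#' @param n number of frames (must exceed the number of planted directions
#'   when `whiten = TRUE`).
#' @param noise_sd additional i.i.d. Gaussian noise in mm (default 0).
#' @param whiten logical; empirically whiten the scores (default `TRUE`).
#' @param seed integer seed.
#' @return A `(n, coordinates)` matrix with named columns.
#' @export
simulate_model_frames <- function(model, n, noise_sd = 0, whiten = TRUE,
                                  seed = 1L) {
  stopifnot(inherits(model, "ground_truth_model"))
  L <- cbind(model$loadings, model$nuisance_loadings)
  K <- ncol(L)
  if (whiten && n <= K + 1L)
    abort_artic("need more than %d frames to whiten %d score dimensions",
                K + 1L, K)
  with_seed(seed, {
    S <- matrix(stats::rnorm(n * K), n, K)
    E <- if (noise_sd > 0)
      matrix(stats::rnorm(n * nrow(L), sd = noise_sd), n, nrow(L))
    else 0
  })
  if (whiten) {
    S <- sweep(S, 2L, colMeans(S))
    S <- S %*% backsolve(chol(crossprod(S) / (n - 1L)), diag(K))
  }
  X <- tcrossprod(S, L) + E
  X <- sweep(X, 2L, model$mean, `+`)
  colnames(X) <- model$coords
  X
}

#' Seeded SAMPA phone-to-posture codebook
#'
#' Assigns every SAMPA label a fixed articulatory target vector drawn
#' uniformly in `[-2, 2]` per parameter (silence `"_"` maps to the
#' neutral posture).  Realistic phonetics is irrelevant for validating the
#' machinery; what matters is that targets are fixed, distinct and
#' recoverable.
#'
#' @param model a `ground_truth_model`.
#' @param labels SAMPA labels to include (default: a 43-symbol
#'   Australian-English-like inventory).
#' @return A `(parameters, labels)` matrix of target postures.
#' @export
phone_codebook <- function(model, labels = sampa_inventory()) {
  M <- length(model$parameter_names)
  with_seed(model$codebook_seed, {
    cb <- matrix(stats::runif(M * length(labels), -2, 2), M,
                 dimnames = list(model$parameter_names, labels))
  })
  if ("_" %in% labels) cb[, "_"] <- 0
  cb
}

#' A SAMPA-style phone inventory
#' @return Character vector of labels, silence `"_"` first.
#' @export
sampa_inventory <- function() {
  c("_", "p", "b", "t", "d", "k", "g", "m", "n", "N", "f", "v", "T", "D",
    "s", "z", "S", "Z", "h", "tS", "dZ", "r", "l", "w", "j", "i:", "I",
    "e", "E", "{", "A:", "O", "U", "u:", "V", "@", "eI", "aI", "OI",
    "@U", "aU", "I@", "e@", "U@")
}

# master grid rate: divisible by both stream rates (300 = lcm(100, 60))
master_rate <- 300L

#' Simulate one multimodal sentence recording
#'
#' The true parameter trajectory holds each phone's target posture and
#' moves between targets with a raised-cosine ramp (at most 80 ms, at most
#' half of each adjacent phone), then is low-pass filtered at 8 Hz -- a
#' deliberately nonlinear trajectory that key-frame interpolation cannot
#' reproduce.  Slow sinusoidal rigid head motion about a fixed neck point
#' is composed on top; the EMA stream (tongue + nasion/tragus) is sampled
#' at 100 Hz and the mocap stream (face + headset) at 60 Hz on a shared
#' clock, with i.i.d. Gaussian sensor noise and Bernoulli missing samples.
#'
#' @param model a [make_ground_truth_model()] result.
#' @param phones character vector of SAMPA labels (must be in the
#'   codebook).
#' @param durations per-phone durations in seconds (positive).
#' @param seed integer seed for noise, head motion and missingness.
#' @param utterance_id id for the generated entry.
#' @param noise_sd,head_motion_amplitude,missing_rate override the values
#'   in the model's [ground_truth_spec()].
#' @return A list with `utterance_id`, `seg` ([phone_segmentation()]),
#'   `ema` (100 Hz [sensor_series()]), `mocap` (60 Hz [sensor_series()])
#'   and `truth` (true 60 Hz [trajectory_matrix()], true [rigid_motion()],
#'   and the model).
#' @export
simulate_sentence <- function(model, phones, durations, seed = 1L,
                              utterance_id = "utt",
                              noise_sd = NULL, head_motion_amplitude = NULL,
                              missing_rate = NULL) {
  stopifnot(inherits(model, "ground_truth_model"))
  spec <- model$spec
  noise_sd <- noise_sd %||% spec$noise_sd
  amp <- head_motion_amplitude %||% spec$head_motion_amplitude
  missing_rate <- missing_rate %||% spec$missing_rate
  if (any(durations <= 0)) abort_artic("phone durations must be positive")
  cb <- phone_codebook(model)
  unknown <- setdiff(phones, colnames(cb))
  if (length(unknown))
    abort_artic("no target posture for phone label(s): %s",
                paste(unknown, collapse = ", "))
  seg <- phone_segmentation(phones, cumsum(durations), utterance_id)
  dur <- sum(durations)
  n_master <- round_half_up(dur * master_rate)
  t_master <- (seq_len(n_master) - 1L) / master_rate
  M <- length(model$parameter_names)
  targets <- cb[, phones, drop = FALSE]
  alpha <- posture_trajectory(targets, seg$end, t_master)
  if (n_master >= min_filter_length(6L))
    alpha <- t(lowpass_cols(t(alpha), master_rate, 8, 6L))
  alpha <- pmin(pmax(alpha, -3), 3)
  # head-frame positions of every sensor on the master grid
  lay <- model$layout
  all_names <- rownames(lay$positions)
  base <- lay$positions
  face_idx <- match(lay$face, all_names)
  head_frame <- array(rep(base, each = n_master),
                      c(n_master, nrow(base), 3L))
  disp <- t(model$loadings %*% alpha)          # n_master x D
  for (j in seq_along(face_idx))
    head_frame[, face_idx[j], ] <- head_frame[, face_idx[j], ] +
      disp[, 3L * j - 2:0] -
      rep(base[face_idx[j], ], each = n_master) +
      rep(model$mean[3L * j - 2:0], each = n_master)
  with_seed(seed, {
    freqs <- stats::runif(6L, 0.1, 0.4)
    phases <- stats::runif(6L, 0, 2 * pi)
    amps <- c(stats::runif(3L, 0.5, 1) * amp[1L],
              stats::runif(3L, 0.5, 1) * amp[2L])
    ema_noise_seed <- sample.int(.Machine$integer.max, 1L)
    mocap_noise_seed <- sample.int(.Machine$integer.max, 1L)
  })
  rigid_at <- function(t) {
    vapply(seq_len(6L), function(j)
      amps[j] * sin(2 * pi * freqs[j] * t + phases[j]), numeric(length(t)))
  }
  rp_master <- rigid_at(t_master)
  world <- rigid_pose_batch(head_frame, rp_master, lay$neck_center)
  sample_stream <- function(sensors, rate, nseed) {
    step <- master_rate / rate
    idx <- seq(1L, n_master, by = step)
    sidx <- match(sensors, all_names)
    pos <- world[idx, sidx, , drop = FALSE]
    n <- length(idx)
    with_seed(nseed, {
      if (noise_sd > 0)
        pos <- pos + array(stats::rnorm(length(pos), sd = noise_sd), dim(pos))
      mask <- matrix(stats::runif(n * length(sidx)) >= missing_rate,
                     n, length(sidx))
    })
    sensor_series(pos, rate, sensors, times = t_master[idx], mask = mask)
  }
  ema <- sample_stream(lay$ema, 100, ema_noise_seed)
  mocap <- sample_stream(lay$mocap, 60, mocap_noise_seed)
  idx60 <- seq(1L, n_master, by = master_rate / 60L)
  truth_traj <- trajectory_matrix(alpha[, idx60, drop = FALSE], 60,
                                  model$parameter_names)
  truth_rigid <- rigid_motion(rp_master[idx60, , drop = FALSE],
                              t_master[idx60], lay$neck_center)
  list(utterance_id = utterance_id, seg = seg, ema = ema, mocap = mocap,
       truth = list(traj = truth_traj, rigid = truth_rigid, model = model))
}

#' Piecewise posture trajectory with raised-cosine transitions
#' @noRd
posture_trajectory <- function(targets, ends, t) {
  n_ph <- ncol(targets)
  M <- nrow(targets)
  starts <- c(0, ends[-n_ph])
  durs <- ends - starts
  alpha <- matrix(0, M, length(t))
  # hold the first target, then ramp at each boundary
  alpha[] <- targets[, 1L]
  if (n_ph > 1L) {
    for (b in seq_len(n_ph - 1L)) {
      tb <- ends[b]
      tau <- min(0.08, durs[b] / 2, durs[b + 1L] / 2)
      prev <- targets[, b]
      nxt <- targets[, b + 1L]
      lo <- tb - tau / 2; hi <- tb + tau / 2
      w <- ifelse(t <= lo, 0,
                  ifelse(t >= hi, 1, 0.5 * (1 - cos(pi * (t - lo) / tau))))
      alpha <- alpha + outer(nxt - prev, w)
    }
  }
  alpha
}

#' Simulate a multimodal corpus
#'
#' Generates `n_sentences` recordings of fixed session length (default
#' 10 s) with random phone sequences from the codebook inventory, and
#' optionally writes the on-disk corpus: one `.lab` segmentation, one true
#' trajectory CSV and two sensor CSVs per sentence, plus a manifest.
#'
#' @param model a [make_ground_truth_model()] result.
#' @param n_sentences number of sentences (>= 1).
#' @param duration session length per sentence in seconds (default 10).
#' @param seed integer seed; sentence `i` uses a sub-seed derived from it.
#' @param out_dir optional output directory; created if needed.
#' @return A list of class `simulated_corpus`: `sentences` (each as in
#'   [simulate_sentence()]), `model`, and -- when `out_dir` is given --
#'   `manifest` (data frame of written files).
#' @export
simulate_corpus <- function(model, n_sentences, duration = 10, seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(model, "ground_truth_model"))
  if (n_sentences < 1L) abort_artic("'n_sentences' must be >= 1")
  labels <- setdiff(colnames(phone_codebook(model)), "_")
  sentences <- vector("list", n_sentences)
  for (i in seq_len(n_sentences)) {
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    with_seed(sub_seed, {
      n_ph <- sample(18:30, 1L)
      phones <- c("_", sample(labels, n_ph, replace = TRUE), "_")
      d <- stats::runif(n_ph + 2L, 0.5, 1.5)
      d[c(1L, n_ph + 2L)] <- d[c(1L, n_ph + 2L)] * 2  # longer silences
    })
    d <- d / sum(d) * duration
    sentences[[i]] <- simulate_sentence(model, phones, d,
                                        seed = sub_seed + 1L,
                                        utterance_id = sprintf("sent%04d", i))
  }
  out <- structure(list(sentences = sentences, model = model),
                   class = "simulated_corpus")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rows <- list()
    for (s in sentences) {
      id <- s$utterance_id
      files <- c(lab = file.path(out_dir, paste0(id, ".lab")),
                 traj = file.path(out_dir, paste0(id, "_traj.csv")),
                 ema = file.path(out_dir, paste0(id, "_ema.csv")),
                 mocap = file.path(out_dir, paste0(id, "_mocap.csv")))
      write_segmentation(s$seg, files[["lab"]])
      write_trajectory(s$truth$traj, files[["traj"]])
      write_sensor_series(s$ema, files[["ema"]])
      write_sensor_series(s$mocap, files[["mocap"]])
      rows[[id]] <- data.frame(utterance_id = id,
                               file = unname(files),
                               kind = names(files),
                               md5 = unname(tools::md5sum(unname(files))))
    }
    manifest <- do.call(rbind, c(rows, make.row.names = FALSE))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    out$manifest <- manifest
  }
  out
}

#' @export
print.simulated_corpus <- function(x, ...) {
  n <- length(x$sentences)
  frames <- sum(vapply(x$sentences, function(s) n_frames(s$mocap), 0))
  cat(sprintf("Simulated corpus: %d sentences, %d mocap frames @ 60 Hz\n",
              n, frames))
  invisible(x)
}

#' Total mocap frame count of a simulated corpus
#' @param corpus a `simulated_corpus`.
#' @return Integer total number of 60 Hz frames.
#' @export
corpus_mocap_frames <- function(corpus) {
  sum(vapply(corpus$sentences, function(s) n_frames(s$mocap), 0))
}
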