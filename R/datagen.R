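# Paired corrupted/truth training-data synthesis: spiral undersampling of
# clean cine frames, augmentation, and 24-frame 128x128 block packaging.

#' Precompute per-frame trajectories and density weights
#'
#' The golden-angle schedule never repeats, so each frame has its own arm
#' rotation set; weights are calibrated once on the first frame's geometry
#' and reused (arm rotations do not change the density profile).
#'
#' @param arm [design_vd_arm()].
#' @param params [acq_params()].
#' @param n_frames Number of frames.
#' @param ... Passed to [density_compensation()].
#' @return List of `list(traj, w)` per frame.
#' @export
make_frame_sampling <- function(arm, params, n_frames, ...) {
  first <- frame_trajectory(arm, 0, params)
  w0 <- density_compensation(first, params, ...)
  scale0 <- sum(w0)
  lapply(seq_len(n_frames) - 1L, function(f) {
    tr <- frame_trajectory(arm, f, params)
    if (f == 0L) return(list(traj = first, w = w0))
    w <- density_compensation(tr, params, calibrate = FALSE, ...)
    list(traj = tr, w = w * scale0 / sum(w))
  })
}

#' Synthetically undersample a cine with the spiral trajectory
#'
#' Per frame: nonuniform Fourier sampling of the clean complex frame along
#' the frame's rotated-arm trajectory, then density-compensated adjoint
#' gridding back. The output carries the spiral aliasing of the prescribed
#' acceleration.
#'
#' @param frames Complex array `H x W x n` (e.g. [cine_complex()]).
#' @param sampling [make_frame_sampling()] list (length >= n).
#' @param voxel_mm Pixel size in mm.
#' @param noise_sd Complex Gaussian noise s.d. added to k-space samples,
#'   relative to the mean magnitude of the frame's samples (0 = none).
#' @return Complex array of aliased frames, same dim as `frames`.
#' @export
synth_undersample <- function(frames, sampling, voxel_mm, noise_sd = 0) {
  d <- dim(frames)
  if (length(sampling) < d[3]) stop("trajectory/frame count mismatch")
  out <- array(0 + 0i, dim = d)
  for (f in seq_len(d[3])) {
    tr <- sampling[[f]]$traj; w <- sampling[[f]]$w
    s <- nufft_sample(frames[, , f], tr$k, voxel_mm)
    if (noise_sd > 0) {
      sc <- noise_sd * mean(abs(s))
      s <- s + complex(real = stats::rnorm(length(s), 0, sc),
                       imaginary = stats::rnorm(length(s), 0, sc))
    }
    out[, , f] <- nufft_grid(s, w, tr$k, voxel_mm, d[1:2])
  }
  out
}

#' A corrupted/truth training pair
#'
#' @param corrupted,truth Complex arrays `crop x crop x block`.
#' @param meta List of provenance fields.
#' @return Object of class `training_pair`.
#' @export
training_pair <- function(corrupted, truth, meta = list()) {
  stopifnot(all(dim(corrupted) == dim(truth)))
  structure(list(corrupted = corrupted, truth = truth, meta = meta),
            class = "training_pair")
}

#' Cut a cine pair into normalized training blocks
#'
#' Non-overlapping blocks of `block` frames, centre-cropped to
#' `crop x crop`; both members are divided by the corrupted member's
#' 99th-percentile magnitude so they share one intensity scale.
#'
#' @param corrupted,truth Complex arrays `H x W x n`.
#' @param block Frames per block (default 24).
#' @param crop Spatial crop (default 128).
#' @param source_id Identifier stored in each pair's `meta`.
#' @return List of [training_pair()]s (empty, with a warning, if `n < block`).
#' @export
make_blocks <- function(corrupted, truth, block = 24, crop = 128,
                        source_id = "") {
  d <- dim(truth)
  if (d[3] < block) {
    warning("series shorter than one block; skipped")
    return(list())
  }
  if (crop > d[1] || crop > d[2]) stop("crop exceeds grid")
  y0 <- (d[1] - crop) %/% 2L; x0 <- (d[2] - crop) %/% 2L
  ys <- y0 + seq_len(crop); xs <- x0 + seq_len(crop)
  n_blocks <- d[3] %/% block
  lapply(seq_len(n_blocks), function(b) {
    fr <- (b - 1L) * block + seq_len(block)
    co <- corrupted[ys, xs, fr, drop = FALSE]
    tr <- truth[ys, xs, fr, drop = FALSE]
    sc <- stats::quantile(abs(co), 0.99, names = FALSE)
    if (sc <= 0) sc <- 1
    training_pair(co / sc, tr / sc,
                  meta = list(source = source_id, block = b, scale = sc))
  })
}

roll3 <- function(a, shift, dim3 = TRUE) {
  n <- dim(a)[3]
  idx <- ((seq_len(n) - 1L - shift) %% n) + 1L
  a[, , idx, drop = FALSE]
}

rot90_frames <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  d <- dim(a)
  out <- a
  for (f in seq_len(d[3])) {
    m <- a[, , f]
    for (j in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
    out[, , f] <- m
  }
  out
}

shift2 <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  m[((seq_len(H) - 1L - dy) %% H) + 1L, ((seq_len(W) - 1L - dx) %% W) + 1L,
    drop = FALSE]
}

#' Randomly augment a training pair
#'
#' Applies an identical transform to both members: random flips, rotations
#' by multiples of 90 degrees, circular time roll, a smooth random
#' second-order polynomial phase offset (|phase| <= pi/2 across the crop),
#' and -- with probability `p_translate` -- a sinusoidal translational
#' drift of up to `max_drift_px` pixels to emulate exercise motion.
#'
#' @param pair [training_pair()].
#' @param p_translate Probability of the translation augmentation.
#' @param max_drift_px Peak drift amplitude in pixels.
#' @param mask Optional logical block transformed alongside (returned in
#'   `meta$mask`), used to keep segmentation labels aligned.
#' @return Augmented [training_pair()]; `meta$augment` records the draw.
#' @export
augment_pair <- function(pair, p_translate = 0.5, max_drift_px = 4,
                         mask = NULL) {
  d <- dim(pair$truth)
  flip_h <- stats::runif(1) < 0.5; flip_v <- stats::runif(1) < 0.5
  rotk <- sample(0:3, 1)
  roll <- sample(seq_len(d[3]), 1) - 1L
  do_tr <- stats::runif(1) < p_translate
  # smooth phase offset: random 2nd-order polynomial scaled to |.| <= pi/2
  cf <- matrix(stats::rnorm(9), 3, 3); cf[outer(0:2, 0:2, "+") > 2] <- 0
  ph <- maxwell_phase(maxwell_model(cf), d[1:2])
  ph <- ph * (pi / 2) / max(abs(ph), 1e-12)
  drift <- if (do_tr) {
    amp <- stats::runif(1, 1, max_drift_px)
    phase0 <- stats::runif(1, 0, 2 * pi)
    per <- stats::runif(1, d[3] / 2, 2 * d[3])
    round(amp * sin(2 * pi * seq_len(d[3]) / per + phase0))
  } else rep(0L, d[3])
  tf <- function(a, is_phase_target = FALSE) {
    if (flip_h) a <- a[, d[2]:1, , drop = FALSE]
    if (flip_v) a <- a[d[1]:1, , , drop = FALSE]
    a <- rot90_frames(a, rotk)
    a <- roll3(a, roll)
    if (do_tr) for (f in seq_len(d[3])) a[, , f] <- shift2(a[, , f], drift[f], 0L)
    if (is_phase_target) a <- a * rep(exp(1i * ph), d[3])
    a
  }
  out <- training_pair(tf(pair$corrupted, TRUE), tf(pair$truth, TRUE),
                       meta = pair$meta)
  out$meta$augment <- list(flip_h = flip_h, flip_v = flip_v, rot90 = rotk,
                           roll = roll, translated = do_tr)
  if (!is.null(mask)) out$meta$mask <- (Re(tf(mask * (1 + 0i))) > 0.5)
  out
}

#' Disjoint train/validation/test split by source id
#'
#' Mirrors the cohort bookkeeping of the training design (e.g. 470/30/16):
#' ids are shuffled deterministically and assigned without overlap.
#'
#' @param ids Character or integer vector of source identifiers.
#' @param n_train,n_val,n_test Split sizes; must sum to `length(ids)` or less.
#' @param seed Shuffle seed.
#' @return List with `train`, `val`, `test`.
#' @export
split_ids <- function(ids, n_train, n_val, n_test, seed = 1) {
  stopifnot(n_train + n_val + n_test <= length(ids))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sh <- sample(ids)
  list(train = sh[seq_len(n_train)],
       val = sh[n_train + seq_len(n_val)],
       test = sh[n_train + n_val + seq_len(n_test)])
}
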