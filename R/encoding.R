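# Coil handling, velocity encoding/decoding, pair combination and
# polynomial (Maxwell-style) background-phase correction.

#' Synthetic coil sensitivity maps
#'
#' Smooth complex Gaussian-lobe sensitivities centred on the FOV perimeter,
#' each with a gentle linear phase, normalized to unit root-sum-of-squares.
#' Used by the phantom simulations; `n_coils = 1` gives a map identically 1.
#'
#' @param n_coils Number of coils (>= 1).
#' @param shape `c(H, W)` grid.
#' @param sigma_frac Lobe width as a fraction of the FOV (default 0.6).
#' @param seed Optional seed controlling the (tiny) random phase slopes.
#' @return Complex array `H x W x n_coils` with RSS = 1 everywhere.
#' @export
synth_coil_maps <- function(n_coils, shape, sigma_frac = 0.6, seed = NULL) {
  stopifnot(n_coils >= 1)
  H <- shape[1]; W <- shape[2]
  if (n_coils == 1L)
    return(array(1 + 0i, dim = c(H, W, 1L)))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  y <- matrix(seq_len(H), H, W); x <- matrix(seq_len(W), H, W, byrow = TRUE)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  sig <- sigma_frac * max(H, W)
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
  maps <- array(0 + 0i, dim = c(H, W, n_coils))
  for (c in seq_len(n_coils)) {
    py <- cy + 0.55 * H * sin(ang[c]); px <- cx + 0.55 * W * cos(ang[c])
    mag <- exp(-((y - py)^2 + (x - px)^2) / (2 * sig^2))
    slope <- if (is.null(seed)) c(0, 0) else stats::runif(2, -0.5, 0.5)
    ph <- 2 * pi * (slope[1] * (y - cy) / H + slope[2] * (x - cx) / W) + ang[c]
    maps[, , c] <- mag * exp(1i * ph)
  }
  rss <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
  for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / rss
  maps
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Estimate coil maps from the first gridded frames
#'
#' Temporal-average method: coil images are averaged over the supplied
#' frames, smoothed with a Gaussian (sigma 2 px on real and imaginary
#' parts), and divided by their root-sum-of-squares magnitude.
#'
#' @param frames Complex array `H x W x n_coils x n_frames` (the trailing
#'   dimension may be dropped for a single frame).
#' @param sigma Smoothing width in pixels.
#' @return Complex array `H x W x n_coils`, RSS-normalized in support.
#' @export
estimate_coil_maps <- function(frames, sigma = 2) {
  d <- dim(frames)
  if (length(d) == 3L) frames <- array(frames, dim = c(d, 1L))
  d <- dim(frames)
  avg <- array(0 + 0i, dim = d[1:3])
  for (c in seq_len(d[3])) {
    m <- matrix(0 + 0i, d[1], d[2])
    for (f in seq_len(d[4])) m <- m + frames[, , c, f]
    m <- m / d[4]
    kern <- gauss_kernel_1d(sigma)
    avg[, , c] <- cpp_gauss_blur2(Re(m), kern) + 1i * cpp_gauss_blur2(Im(m), kern)
  }
  rss <- sqrt(apply(abs(avg)^2, c(1, 2), sum))
  if (max(rss) == 0) stop("degenerate input: all-zero frames")
  rss[rss < 1e-12 * max(rss)] <- Inf
  for (c in seq_len(d[3])) avg[, , c] <- avg[, , c] / rss
  avg
}

gauss_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Conjugate-weighted coil combination
#'
#' `sum_c conj(map_c) img_c / sum_c |map_c|^2`, with zero output where the
#' map RSS vanishes.
#'
#' @param imgs Complex array `H x W x n_coils`.
#' @param maps Matching coil maps.
#' @return Complex H x W frame.
#' @export
coil_combine <- function(imgs, maps) {
  if (!all(dim(imgs) == dim(maps))) stop("image/map shape mismatch")
  num <- matrix(0 + 0i, dim(imgs)[1], dim(imgs)[2])
  den <- matrix(0, dim(imgs)[1], dim(imgs)[2])
  for (c in seq_len(dim(imgs)[3])) {
    num <- num + Conj(maps[, , c]) * imgs[, , c]
    den <- den + abs(maps[, , c])^2
  }
  out <- num
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out[!ok] <- 0
  out
}

#' Velocity-encode a magnitude/velocity image into an encoding pair
#'
#' One-sided encoding: the flow-compensated frame carries only the
#' background phase `phi0`; the flow-encoded frame adds
#' `pi * velocity / venc` (wrapped), so VENC maps to a phase of pi.
#'
#' @param magnitude Real H x W magnitude image.
#' @param velocity Through-plane velocity map in cm/s (may exceed VENC;
#'   it then wraps).
#' @param phi0 Background phase in radians (scalar or H x W).
#' @param venc Velocity-encoding limit in cm/s (> 0).
#' @return Object of class `encoding_pair`: complex `comp`, `enc`, `venc_cm_s`.
#' @export
encode_velocity <- function(magnitude, velocity, phi0 = 0, venc = 200) {
  if (venc <= 0) stop("venc must be positive")
  stopifnot(all(dim(magnitude) == dim(velocity)))
  comp <- magnitude * exp(1i * phi0)
  enc <- magnitude * exp(1i * (phi0 + pi * velocity / venc))
  structure(list(comp = comp, enc = enc, venc_cm_s = venc),
            class = "encoding_pair")
}

#' Low-order polynomial background-phase model
#'
#' Phase surface `sum coeffs[i,j] * yn^i * xn^j` (degree <= 2 total) on
#' normalized coordinates `yn, xn` in [-1, 1], standing in for concomitant-
#' gradient (Maxwell) terms. Used subtractively in [combine_pair()].
#'
#' @param coeffs 3 x 3 coefficient matrix; entries with `i + j > 2` must be 0.
#' @return Object of class `maxwell_model`.
#' @export
maxwell_model <- function(coeffs) {
  coeffs <- as.matrix(coeffs)
  stopifnot(all(dim(coeffs) == c(3, 3)))
  deg <- outer(0:2, 0:2, "+")
  if (any(coeffs[deg > 2] != 0)) stop("polynomial degree must be <= 2")
  structure(list(coeffs = coeffs), class = "maxwell_model")
}

#' Evaluate a background-phase model on a grid
#'
#' @param model [maxwell_model()].
#' @param shape `c(H, W)`.
#' @return H x W matrix of phase in radians.
#' @export
maxwell_phase <- function(model, shape) {
  H <- shape[1]; W <- shape[2]
  yn <- (2 * (seq_len(H) - 1) / (H - 1)) - 1
  xn <- (2 * (seq_len(W) - 1) / (W - 1)) - 1
  ph <- matrix(0, H, W)
  for (i in 0:2) for (j in 0:2)
    if (model$coeffs[i + 1, j + 1] != 0)
      ph <- ph + model$coeffs[i + 1, j + 1] * outer(yn^i, xn^j)
  ph
}

wrap_phase <- function(p) {
  w <- (p + pi) %% (2 * pi) - pi
  # map -pi to +pi so the range is (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Combine an encoding pair into a phase-contrast frame
#'
#' Magnitude is the average of the two encodings; phase is the wrapped
#' phase difference `angle(enc * conj(comp))` minus an optional polynomial
#' background-phase surface.
#'
#' @param pair [encode_velocity()] output (or any list with `comp`, `enc`).
#' @param maxwell Optional [maxwell_model()] subtracted from the phase.
#' @return Complex H x W frame `magnitude * exp(i phase)`.
#' @export
combine_pair <- function(pair, maxwell = NULL) {
  mag <- (abs(pair$comp) + abs(pair$enc)) / 2
  ph <- Arg(pair$enc * Conj(pair$comp))
  if (!is.null(maxwell)) ph <- wrap_phase(ph - maxwell_phase(maxwell, dim(mag)))
  mag * exp(1i * ph)
}

#' Convert phase-difference to velocity, and back
#'
#' `v = venc * phase / pi`; the inverse wraps the phase so recovered
#' velocities lie in `(-venc, venc]`.
#'
#' @param phase Phase in radians (any shape).
#' @param venc Velocity-encoding limit in cm/s.
#' @return Velocity in cm/s.
#' @export
phase_to_velocity <- function(phase, venc) venc * phase / pi

#' @rdname phase_to_velocity
#' @param velocity Velocity in cm/s.
#' @export
velocity_to_phase <- function(velocity, venc) wrap_phase(pi * velocity / venc)
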