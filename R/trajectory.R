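#' Acquisition parameters for the real-time spiral phase-contrast scan
#'
#' Container for the scan geometry and timing used throughout the package.
#' Defaults reproduce the real-time protocol: 400 mm field of view, 2.1 mm
#' in-plane voxels, TR/TE 5.8/2.1 ms, 35 ms temporal resolution, three
#' spiral interleaves per frame and a velocity-encoding limit of 200 cm/s.
#'
#' @param fov_mm Field of view in mm (square).
#' @param voxel_mm In-plane voxel size in mm; `k_max = 1/(2 voxel_mm)`.
#' @param tr_ms,te_ms Repetition / echo time in ms.
#' @param venc_cm_s Velocity-encoding limit in cm/s.
#' @param arms_per_frame Spiral interleaves combined per frame.
#' @param frame_ms Frame duration (temporal resolution) in ms.
#' @param flip_deg Flip angle in degrees (carried, not used numerically).
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(fov_mm = 400, voxel_mm = 2.1, tr_ms = 5.8, te_ms = 2.1,
                       venc_cm_s = 200, arms_per_frame = 3, frame_ms = 35.0,
                       flip_deg = 20) {
  stopifnot(fov_mm > 0, voxel_mm > 0, arms_per_frame >= 1, frame_ms > 0,
            venc_cm_s > 0)
  structure(list(fov_mm = fov_mm, voxel_mm = voxel_mm, tr_ms = tr_ms,
                 te_ms = te_ms, venc_cm_s = venc_cm_s,
                 arms_per_frame = arms_per_frame, frame_ms = frame_ms,
                 flip_deg = flip_deg, k_max = 1 / (2 * voxel_mm)),
            class = "acq_params")
}

#' Variable-density profile of the spiral arm
#'
#' The arm's radial pitch (gap between successive turns, times the FOV)
#' equals `arm_accel_inner` inside the central plateau, `arm_accel_outer`
#' in the outer plateau, and interpolates linearly in between. The default
#' profile undersamples the outer k-space 2.5x less densely than the
#' centre (26x vs 65x per arm).
#'
#' @param r_inner_frac,r_outer_frac Plateau boundaries as fractions of `k_max`.
#' @param arm_accel_inner,arm_accel_outer Per-arm acceleration on each plateau.
#' @param transition Only `"linear"` is supported.
#' @return An object of class `density_spec`.
#' @export
density_spec <- function(r_inner_frac = 0.2, r_outer_frac = 0.9,
                         arm_accel_inner = 26, arm_accel_outer = 65,
                         transition = "linear") {
  if (!(r_inner_frac > 0 && r_inner_frac < r_outer_frac && r_outer_frac <= 1))
    stop("invalid density spec: need 0 < r_inner_frac < r_outer_frac <= 1")
  if (!(arm_accel_inner > 0 && arm_accel_outer >= arm_accel_inner))
    stop("invalid density spec: acceleration must be positive and non-decreasing")
  transition <- match.arg(transition, "linear")
  structure(list(r_inner_frac = r_inner_frac, r_outer_frac = r_outer_frac,
                 arm_accel_inner = arm_accel_inner,
                 arm_accel_outer = arm_accel_outer, transition = transition),
            class = "density_spec")
}

# per-arm radial pitch (x FOV) at normalized radius rho
arm_pitch <- function(rho, spec) {
  ri <- spec$r_inner_frac; ro <- spec$r_outer_frac
  a <- spec$arm_accel_inner; b <- spec$arm_accel_outer
  ifelse(rho <= ri, a,
         ifelse(rho >= ro, b, a + (b - a) * (rho - ri) / (ro - ri)))
}

#' Design a variable-density spiral arm
#'
#' Integrates the pitch equation `dr/dtheta = R(r/k_max) / (2 pi fov)` with
#' fixed-step RK4 from the k-space centre to `k_max`, then resamples the
#' path at `n_samples` points uniform in arc length. `R(rho)` is the
#' per-arm acceleration profile of [density_spec()].
#'
#' @param params [acq_params()].
#' @param spec [density_spec()].
#' @param n_samples Samples along the arm (>= 64).
#' @return An object of class `spiral_arm` with fields `k` (n x 2 matrix of
#'   kx, ky in cycles/mm, centre outward), `r`, `theta` (unwrapped),
#'   `n_samples`, `turns`, plus the generating `params` and `spec`.
#' @export
design_vd_arm <- function(params, spec, n_samples = 2048) {
  stopifnot(inherits(params, "acq_params"), inherits(spec, "density_spec"),
            n_samples >= 64)
  kmax <- params$k_max; fov <- params$fov_mm
  f <- function(r) arm_pitch(pmin(r / kmax, 1), spec) / (2 * pi * fov)
  dth <- 2 * pi / 8192
  # generous upper bound on steps: pitch >= inner accel everywhere
  max_steps <- ceiling(2 * pi * fov * kmax / spec$arm_accel_inner / dth) + 10L
  th <- numeric(max_steps + 1L); r <- numeric(max_steps + 1L)
  i <- 1L
  while (r[i] < kmax && i <= max_steps) {
    k1 <- f(r[i]); k2 <- f(r[i] + dth / 2 * k1)
    k3 <- f(r[i] + dth / 2 * k2); k4 <- f(r[i] + dth * k3)
    r[i + 1L] <- r[i] + dth / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    th[i + 1L] <- th[i] + dth
    i <- i + 1L
  }
  th <- th[1:i]; r <- r[1:i]
  if (r[i] > kmax) {  # clip final step at k_max by linear interpolation
    frac <- (kmax - r[i - 1L]) / (r[i] - r[i - 1L])
    th[i] <- th[i - 1L] + frac * dth
    r[i] <- kmax
  }
  dr <- diff(r); dt2 <- diff(th)
  seg <- sqrt((r[-length(r)] + dr / 2)^2 * dt2^2 + dr^2)
  s <- c(0, cumsum(seg))
  s_t <- seq(0, s[length(s)], length.out = n_samples)
  th_s <- stats::approx(s, th, xout = s_t)$y
  r_s <- stats::approx(s, r, xout = s_t)$y
  structure(list(k = cbind(kx = r_s * cos(th_s), ky = r_s * sin(th_s)),
                 r = r_s, theta = th_s, n_samples = n_samples,
                 turns = th[length(th)] / (2 * pi),
                 params = params, spec = spec),
            class = "spiral_arm")
}

#' Golden-angle rotation schedule
#'
#' Deterministic, stateless angle sequence: arm `n` (0-based) is rotated by
#' `(n * ga) %% 2 pi`. The default increment is the full-circle golden angle
#' `2 pi / phi` (about 222.49 deg); pass `ga = 2 * pi * (1 - 1/((1+sqrt(5))/2))`
#' for the 137.51 deg convention.
#'
#' @param n_arms_total Number of arms (>= 1); angles for arms `0..n-1`.
#' @param ga Angular increment in radians.
#' @return Numeric vector of angles in `[0, 2 pi)`.
#' @export
golden_angle_schedule <- function(n_arms_total,
                                  ga = 2 * pi / ((1 + sqrt(5)) / 2)) {
  stopifnot(n_arms_total >= 1)
  ((0:(n_arms_total - 1L)) * ga) %% (2 * pi)
}

#' Assemble the rotated-arm trajectory of one frame
#'
#' Frame `f` uses global arms `3f, 3f+1, 3f+2` (for three arms per frame)
#' of the golden-angle schedule, so successive frames continue the sequence.
#'
#' @param arm [design_vd_arm()] output.
#' @param frame_index 0-based frame index.
#' @param params [acq_params()]; supplies `arms_per_frame`.
#' @param ga Golden-angle increment (see [golden_angle_schedule()]).
#' @return Object of class `frame_traj`: `k` (n x 2), `arm_angles`,
#'   `arm_id` / `sample_id` per-sample provenance, `frame_index`.
#' @export
frame_trajectory <- function(arm, frame_index, params = arm$params,
                             ga = 2 * pi / ((1 + sqrt(5)) / 2)) {
  stopifnot(inherits(arm, "spiral_arm"), frame_index >= 0)
  na <- params$arms_per_frame
  idx <- frame_index * na + 0:(na - 1L)
  ang <- (idx * ga) %% (2 * pi)
  rot <- function(a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    arm$k %*% t(R)
  }
  k <- do.call(rbind, lapply(ang, rot))
  colnames(k) <- c("kx", "ky")
  structure(list(frame_index = frame_index, arm_angles = ang, k = k,
                 arm_id = rep(seq_len(na), each = arm$n_samples),
                 sample_id = rep(seq_len(arm$n_samples), na),
                 params = params),
            class = "frame_traj")
}

#' Density-compensation weights for a frame trajectory
#'
#' Two estimators are provided. `"pipe"` is the iterative sampling-density
#' fixed point: weights are repeatedly divided by their own
#' gridded-and-resampled density, estimated by Kaiser-Bessel convolution
#' (width 4) on an oversampled grid. `"cell"` computes analytic local
#' cell areas for an arc-length-sampled multi-arm spiral: along-arm spacing
#' times the smaller of the azimuthal spacing near DC (`2 pi r / n_arms`,
#' the arms leave the centre as single rays) and the radial inter-turn
#' spacing `R(rho)/n_arms` further out. For heavily undersampled arms whose
#' inter-turn gaps far exceed the convolution kernel, the iterative
#' estimator only senses the along-readout density, so `"cell"` is the
#' better choice and is used by the reconstruction pipeline.
#'
#' Unless `calibrate = FALSE`, weights are rescaled so that the
#' density-weighted adjoint has unit gain on an internal smooth reference
#' (a centred Gaussian of width N/6 pixels), making the absolute scale of
#' gridded images meaningful.
#'
#' @param traj [frame_trajectory()] output (or any object with `k`).
#' @param params [acq_params()].
#' @param n_iter Iterations for `method = "pipe"` (default 10).
#' @param width Kaiser-Bessel kernel width in grid samples.
#' @param osf Grid oversampling factor for the density estimate.
#' @param method `"cell"` (default) or `"pipe"`.
#' @param calibrate Rescale to unit adjoint gain on the internal reference.
#' @param total Optional target for `sum(weights)`; overrides calibration.
#' @return Numeric vector of non-negative weights, one per k-space sample.
#' @export
density_compensation <- function(traj, params, n_iter = 10, width = 4,
                                 osf = 2, method = c("cell", "pipe"),
                                 calibrate = TRUE, total = NULL) {
  method <- match.arg(method)
  k <- traj$k
  stopifnot(nrow(k) >= 1)
  N <- grid_size(params)
  if (nrow(k) == 1L) return(if (is.null(total)) 1 / N^2 else total)
  if (method == "pipe") {
    nos <- as.integer(osf * N)
    g <- k * params$voxel_mm * N * osf   # fine-grid index offsets from DC
    beta <- kb_beta(width, osf)
    w <- rep(1, nrow(k))
    for (it in seq_len(n_iter)) {
      d <- cpp_kb_density(w, g[, 2], g[, 1], nos, nos, width, beta)
      if (any(!is.finite(d)) || any(d <= 0)) {
        warning("density estimate degenerate; returning last iterate")
        break
      }
      w_new <- w / d
      if (any(!is.finite(w_new))) {
        warning("density compensation diverged; returning last iterate")
        break
      }
      w <- w_new
    }
  } else {
    u <- k * params$voxel_mm * N        # cycles per grid FOV
    r_u <- sqrt(rowSums(u^2))
    n_arms <- if (!is.null(traj$arm_id)) max(traj$arm_id) else 1L
    ns_arm <- nrow(k) %/% n_arms
    seg <- sqrt(rowSums((u[2:ns_arm, , drop = FALSE] -
                         u[1:(ns_arm - 1L), , drop = FALSE])^2))
    ds <- rep(c(seg[1], seg), n_arms)
    # radial inter-turn spacing from the arm geometry itself: local
    # 2 pi r'(theta), estimated per sample from the path
    th <- atan2(u[1:ns_arm, 2], u[1:ns_arm, 1])
    r_arm <- r_u[1:ns_arm]
    dth <- diff(th); dth <- (dth + pi) %% (2 * pi) - pi
    drdth <- c(0, diff(r_arm) / pmax(abs(dth), 1e-9))
    drdth[1] <- drdth[2]
    pitch_u <- 2 * pi * abs(drdth)
    pitch_u <- rep(stats::filter(pitch_u, rep(1 / 9, 9), sides = 2) |>
                     (\(z) { z[is.na(z)] <- pitch_u[is.na(z)]; z })(), n_arms)
    w <- ds * pmin(2 * pi * r_u / n_arms, pitch_u / n_arms) / N^2
    w[r_u == 0] <- (ds[r_u == 0] / 2)^2 / N^2
  }
  w[!is.finite(w) | w < 0] <- 0
  if (!is.null(total)) return(w * (total / sum(w)))
  if (calibrate) {
    yy <- outer(((1:N) - N / 2 - 0.5)^2, rep(1, N))
    ref <- exp(-(yy + t(yy)) / (2 * (N / 6)^2))
    sam <- nufft_sample(ref + 0i, k, params$voxel_mm)
    rec <- nufft_grid(sam, w, k, params$voxel_mm, c(N, N))
    gain <- sum(Re(rec * Conj(ref))) / sum(ref^2)
    if (is.finite(gain) && gain > 0) w <- w / gain
  }
  w
}

#' Audit the realized acceleration of a spiral arm
#'
#' Measures the local radial turn spacing of the arm path (2 pi dr/dtheta,
#' evaluated at crossings of fixed-azimuth rays) times the FOV, and averages
#' it over the inner and outer density plateaus. With ~2.5 turns per arm no
#' complete turn lies inside either plateau, so the local spacing -- the
#' quantity the design's per-arm factors describe -- is the well-defined
#' observable. Per-frame values divide by the number of interleaves.
#'
#' @param arm [design_vd_arm()] output.
#' @param params [acq_params()].
#' @param arms_per_frame Interleaves per frame.
#' @param n_rays Number of fixed-azimuth rays used for measurement points.
#' @return List with `per_arm_inner`, `per_arm_outer`, `per_frame_inner`,
#'   `per_frame_outer`, `density_ratio` and the raw per-crossing table.
#' @export
acceleration_audit <- function(arm, params = arm$params,
                               arms_per_frame = params$arms_per_frame,
                               n_rays = 32) {
  stopifnot(inherits(arm, "spiral_arm"))
  kmax <- params$k_max; fov <- params$fov_mm
  th <- arm$theta; r <- arm$r
  # crossings of azimuth rays a + 2 pi m with the unwrapped path
  az <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  th_cross <- unlist(lapply(az, function(a) {
    m <- seq(ceiling((th[1] - a) / (2 * pi)), floor((th[length(th)] - a) / (2 * pi)))
    a + 2 * pi * m
  }))
  th_cross <- sort(th_cross[th_cross > th[2] & th_cross < th[length(th)]])
  r_cross <- stats::approx(th, r, xout = th_cross)$y
  # local dr/dtheta at each crossing via centered secant on the path
  h <- pi / 8
  r_hi <- stats::approx(th, r, xout = pmin(th_cross + h, th[length(th)]))$y
  r_lo <- stats::approx(th, r, xout = pmax(th_cross - h, th[1]))$y
  dth <- pmin(th_cross + h, th[length(th)]) - pmax(th_cross - h, th[1])
  gap <- 2 * pi * (r_hi - r_lo) / dth * fov
  rho <- r_cross / kmax
  inner <- gap[rho <= arm$spec$r_inner_frac & rho > 0]
  outer <- gap[rho >= arm$spec$r_outer_frac]
  m_in <- if (length(inner)) mean(inner) else NA_real_
  m_out <- if (length(outer)) mean(outer) else NA_real_
  list(per_arm_inner = m_in, per_arm_outer = m_out,
       per_frame_inner = m_in / arms_per_frame,
       per_frame_outer = m_out / arms_per_frame,
       density_ratio = m_out / m_in,
       crossings = data.frame(theta = th_cross, rho = rho, gap_x_fov = gap))
}

#' Frames acquired in a continuous scan
#'
#' @param duration_s Scan duration in seconds.
#' @param frame_ms Frame duration in ms.
#' @return Integer frame count (`ceiling`).
#' @export
frames_for_duration <- function(duration_s, frame_ms = 35.0) {
  as.integer(ceiling(duration_s * 1000 / frame_ms))
}

# even reconstruction grid size fully containing the sampled k-space disc
grid_size <- function(params) 2L * as.integer(ceiling(params$fov_mm / params$voxel_mm / 2))

#' Export a set of frame trajectories with weights to CSV
#'
#' One row per k-space sample: frame, arm, sample, kx, ky (cycles/mm), dcf.
#'
#' @param trajs List of [frame_trajectory()] objects.
#' @param dcfs List of matching weight vectors.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajs, dcfs, path) {
  df <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    data.frame(frame = tr$frame_index, arm = tr$arm_id, sample = tr$sample_id,
               kx = tr$k[, 1], ky = tr$k[, 2], dcf = dcfs[[i]])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
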