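# Synthetic pulsatile aortic-flow phantom: circular vessel with parabolic
# through-plane flow, static background tissue, beat-to-beat RR jitter,
# respiratory stroke-volume modulation and translation, and a
# rest/exercise/recovery heart-rate ramp.

#' Configuration of the dynamic flow phantom
#'
#' @param grid Image grid size (H = W, even).
#' @param voxel_mm Pixel size in mm.
#' @param frame_ms Frame duration in ms.
#' @param duration_s Scan duration in seconds.
#' @param hr_bpm Resting heart rate (bpm).
#' @param hr_ramp `c(t_start, t_end, hr_peak)`: exercise begins at
#'   `t_start` s, HR ramps linearly to `hr_peak` at `t_end`, then returns
#'   linearly to `hr_bpm` over the recovery phase. Defaults mirror a
#'   40 s rest / 80 s exercise / 60 s recovery protocol with 68 -> 94 bpm.
#' @param sv_ml Resting stroke volume (mL).
#' @param sv_peak_ml Stroke volume at peak exercise (mL).
#' @param recovery_s Recovery-phase length in seconds.
#' @param resp_period_s Respiratory period (s).
#' @param resp_sv_frac Fractional respiratory SV modulation (0 <= f < 0.5).
#' @param vessel_center Vessel centre as `c(y, x)` fractions of the grid.
#' @param radius_mm Vessel lumen radius in mm.
#' @param wall_mm Vessel wall thickness in mm.
#' @param motion_amp_px Peak respiratory translation (pixels).
#' @param rr_jitter_sd Lognormal sigma of beat-to-beat RR jitter.
#' @param noise_sd Complex noise s.d. (per coil, applied at k-space
#'   simulation; the phantom truth itself is noise-free).
#' @param n_coils Number of receive coils for simulated acquisitions.
#' @param venc_cm_s Velocity-encoding limit carried with the cine.
#' @param seed RNG seed; phantoms are bit-reproducible given the seed.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid = 192, voxel_mm = 2.1, frame_ms = 35.0,
                           duration_s = 30, hr_bpm = 68,
                           hr_ramp = c(40, 120, 94), sv_ml = 80,
                           sv_peak_ml = sv_ml, recovery_s = 60,
                           resp_period_s = 4, resp_sv_frac = 0.05,
                           vessel_center = c(0.55, 0.45), radius_mm = 15,
                           wall_mm = 2, motion_amp_px = 2,
                           rr_jitter_sd = 0.03, noise_sd = 0.02,
                           n_coils = 4, venc_cm_s = 200, seed = 1) {
  stopifnot(radius_mm > 0, resp_sv_frac >= 0, resp_sv_frac < 0.5,
            hr_bpm >= 30, hr_bpm <= 220, grid %% 2 == 0)
  R_px <- radius_mm / voxel_mm
  cy <- vessel_center[1] * grid; cx <- vessel_center[2] * grid
  if (cy - R_px < 1 || cy + R_px > grid || cx - R_px < 1 || cx + R_px > grid)
    stop("invalid config: vessel outside the field of view")
  structure(as.list(environment())[names(formals(phantom_config))],
            class = "phantom_config")
}

#' Instantaneous mean vessel velocity over the cardiac cycle
#'
#' Systolic half-sinusoid over the first 35% of the beat plus a small
#' constant diastolic offset (5% of the systolic peak); continuous in t.
#'
#' @param t_in_beat Cardiac phase in `[0, 1)`.
#' @param v_peak Systolic peak of the spatial-mean velocity (cm/s).
#' @return Mean velocity across the vessel lumen in cm/s.
#' @export
flow_waveform <- function(t_in_beat, v_peak) {
  stopifnot(all(t_in_beat >= 0 & t_in_beat < 1))
  0.05 * v_peak + v_peak * sin(pi * t_in_beat / 0.35) * (t_in_beat < 0.35)
}

# time integral of flow_waveform over one beat, as a fraction of v_peak * T
waveform_integral_frac <- function() 0.05 + 2 * 0.35 / pi

#' Heart rate and stroke volume along the exercise protocol
#'
#' Piecewise-linear rest / exercise / recovery profile.
#'
#' @param t_s Time in seconds (scalar or vector).
#' @param config [phantom_config()].
#' @return List with `hr_bpm` and `sv_ml` at `t_s`.
#' @export
exercise_profile <- function(t_s, config) {
  t1 <- config$hr_ramp[1]; t2 <- config$hr_ramp[2]
  hr_peak <- config$hr_ramp[3]; t3 <- t2 + config$recovery_s
  ramp <- function(rest, peak) {
    up <- rest + (peak - rest) * pmin(pmax((t_s - t1) / max(t2 - t1, 1e-9), 0), 1)
    down <- pmin(pmax((t_s - t2) / max(t3 - t2, 1e-9), 0), 1)
    up + (rest - up) * down
  }
  list(hr_bpm = ramp(config$hr_bpm, hr_peak),
       sv_ml = ramp(config$sv_ml, config$sv_peak_ml))
}

#' Generate a synthetic pulsatile-flow cine with ground truth
#'
#' Builds a circular vessel with a parabolic through-plane velocity profile
#' `v(r, t) = 2 v_mean(t) (1 - (r/R)^2)` inside radius R, static background
#' ellipses with zero velocity, beat-to-beat lognormal RR jitter,
#' sinusoidal respiratory SV modulation and translation, and the
#' rest/exercise/recovery HR ramp. Deterministic under the config seed.
#'
#' @param config [phantom_config()].
#' @return List with `cine` (class `cine_series`: `mag`, `vel` arrays
#'   `H x W x n`, `frame_ms`, `voxel_mm`, `venc_cm_s`, `t_ms`) and `truth`
#'   (class `ground_truth`: `masks`, `flow_ml_s`, `velocity`, `beats`
#'   data frame, `config`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  N <- config$grid; vox <- config$voxel_mm
  n_frames <- as.integer(floor(config$duration_s * 1000 / config$frame_ms))
  area_mm2 <- pi * config$radius_mm^2
  # ---- beat schedule ----
  beats <- list(); t <- 0; i <- 1L
  while (t < config$duration_s + 2) {
    prof <- exercise_profile(t, config)
    rr_ms <- 60000 / prof$hr_bpm * exp(stats::rnorm(1, 0, config$rr_jitter_sd))
    sv <- prof$sv_ml * (1 + config$resp_sv_frac *
                          sin(2 * pi * t / config$resp_period_s))
    beats[[i]] <- c(start_ms = t * 1000, rr_ms = rr_ms, sv_ml = sv)
    t <- t + rr_ms / 1000; i <- i + 1L
  }
  bt <- do.call(rbind, beats)
  v_peak_mean <- bt[, "sv_ml"] /
    (area_mm2 * 0.01 * bt[, "rr_ms"] / 1000 * waveform_integral_frac())
  beats_df <- data.frame(
    start_ms = bt[, "start_ms"], rr_ms = bt[, "rr_ms"],
    peak_time_ms = bt[, "start_ms"] + 0.175 * bt[, "rr_ms"],
    hr_bpm = 60000 / bt[, "rr_ms"], sv_ml = bt[, "sv_ml"],
    co_l_min = bt[, "sv_ml"] * 60000 / bt[, "rr_ms"] / 1000)
  # ---- static anatomy ----
  yy <- matrix(seq_len(N), N, N); xx <- t(yy)
  cy0 <- config$vessel_center[1] * N; cx0 <- config$vessel_center[2] * N
  bg <- 0.45 * (((yy - 0.5 * N) / (0.46 * N))^2 +
                  ((xx - 0.52 * N) / (0.4 * N))^2 < 1) +
        0.15 * (((yy - 0.3 * N) / (0.18 * N))^2 +
                  ((xx - 0.7 * N) / (0.12 * N))^2 < 1) -
        0.1 * (((yy - 0.7 * N) / (0.1 * N))^2 +
                  ((xx - 0.75 * N) / (0.14 * N))^2 < 1)
  R_px <- config$radius_mm / vox; wall_px <- config$wall_mm / vox
  # ---- frames ----
  mag <- array(0, dim = c(N, N, n_frames))
  vel <- array(0, dim = c(N, N, n_frames))
  masks <- array(FALSE, dim = c(N, N, n_frames))
  flow <- numeric(n_frames)
  t_ms <- (seq_len(n_frames) - 0.5) * config$frame_ms
  for (f in seq_len(n_frames)) {
    tf <- t_ms[f] / 1000
    b <- max(which(bt[, "start_ms"] <= t_ms[f] + 1e-9))
    phase <- (t_ms[f] - bt[b, "start_ms"]) / bt[b, "rr_ms"]
    v_mean <- flow_waveform(min(phase, 1 - 1e-12), v_peak_mean[b])
    shift <- config$motion_amp_px * sin(2 * pi * tf / config$resp_period_s)
    cy <- cy0 + shift; cx <- cx0
    d2 <- (yy - cy)^2 + (xx - cx)^2
    lumen <- d2 <= R_px^2
    wall <- d2 <= (R_px + wall_px)^2 & !lumen
    m <- bg
    m[wall] <- 0.25
    m[lumen] <- 1.0
    v <- matrix(0, N, N)
    v[lumen] <- 2 * v_mean * (1 - d2[lumen] / R_px^2)
    mag[, , f] <- m; vel[, , f] <- v; masks[, , f] <- lumen
    flow[f] <- sum(v[lumen]) * vox^2 * 0.01
  }
  cine <- structure(list(mag = mag, vel = vel, frame_ms = config$frame_ms,
                         voxel_mm = vox, venc_cm_s = config$venc_cm_s,
                         t_ms = t_ms), class = "cine_series")
  truth <- structure(list(masks = masks, flow_ml_s = flow, velocity = vel,
                          beats = beats_df, config = config),
                     class = "ground_truth")
  list(cine = cine, truth = truth)
}

#' Complex phase-subtracted representation of a cine
#'
#' `mag * exp(i pi v / venc)` per frame: the form in which clinically
#' stored phase-contrast images enter training-data synthesis.
#'
#' @param cine `cine_series` from [generate_phantom()].
#' @return Complex array `H x W x n`.
#' @export
cine_complex <- function(cine) {
  cine$mag * exp(1i * pi * cine$vel / cine$venc_cm_s)
}
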