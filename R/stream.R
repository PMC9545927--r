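# Sliding-window streaming: block schedule, pair normalization, the
# latency model, simulated multi-coil acquisition, and the end-to-end
# reconstruction/monitoring pipeline.

#' Sliding-window block schedule
#'
#' Blocks of `window` frames starting every `step` frames (with a final
#' block pinned to the stream end). Each block keeps its central `step`
#' frames; the first block also keeps its leading edge frames and the
#' final block its trailing frames, so every frame is kept exactly once.
#' Indices are 0-based, ranges half-open.
#'
#' @param n_frames Stream length (>= window).
#' @param window Block length (default 24).
#' @param step Step size (default 18).
#' @return Object of class `block_schedule`: data frame `start`, `end`,
#'   `kept_start`, `kept_end`.
#' @export
schedule_blocks <- function(n_frames, window = 24, step = 18) {
  if (n_frames < window) stop("need at least one full window of frames")
  lead <- (window - step) %/% 2L
  starts <- seq(0L, n_frames - window, by = step)
  if (starts[length(starts)] + window < n_frames)
    starts <- c(starts, n_frames - window)
  n_b <- length(starts)
  kept_start <- integer(n_b); kept_end <- integer(n_b)
  for (i in seq_len(n_b)) {
    kept_start[i] <- if (i == 1L) 0L else kept_end[i - 1L]
    kept_end[i] <- if (i == n_b) n_frames else starts[i] + lead + step
  }
  structure(data.frame(start = starts, end = starts + window,
                       kept_start = kept_start, kept_end = kept_end),
            class = c("block_schedule", "data.frame"))
}

#' Normalize an encoding-pair block to unit scale
#'
#' Both encodings are divided by their shared 99th-percentile magnitude
#' (real/imaginary parts then clipped to [-1, 1]); the scale is returned
#' so magnitudes can be restored before quantification. Phase -- and thus
#' velocity -- is unaffected by the scaling.
#'
#' @param pair List with complex blocks `comp` and `enc`.
#' @return List `pair` (normalized), `scale`.
#' @export
normalize_block <- function(pair) {
  sc <- stats::quantile(c(abs(pair$comp), abs(pair$enc)), 0.99, names = FALSE)
  if (!is.finite(sc) || sc <= 0) stop("all-zero or degenerate block")
  clip <- function(z) complex(real = pmin(pmax(Re(z), -1), 1),
                              imaginary = pmin(pmax(Im(z), -1), 1)) |>
    array(dim = dim(z))
  list(pair = list(comp = clip(pair$comp / sc), enc = clip(pair$enc / sc),
                   venc_cm_s = pair$venc_cm_s),
       scale = sc)
}

#' Latency/timing model of the streaming reconstruction
#'
#' @param t_init_s Pipeline initialization time (s).
#' @param t_grid_ms Gridding time per frame (ms).
#' @param t_net_ms Network (suppression of both encodings + segmentation)
#'   time per block (ms).
#' @param frame_ms Acquisition time per frame (ms).
#' @return Object of class `timing_model`.
#' @export
timing_model <- function(t_init_s = 16, t_grid_ms = 16.2, t_net_ms = 151,
                         frame_ms = 35.0) {
  stopifnot(t_init_s >= 0, t_grid_ms >= 0, t_net_ms >= 0, frame_ms > 0)
  structure(list(t_init_s = t_init_s, t_grid_ms = t_grid_ms,
                 t_net_ms = t_net_ms, frame_ms = frame_ms),
            class = "timing_model")
}

#' Simulate streaming latency
#'
#' Frames are gridded as acquired; a block completes no earlier than its
#' last frame's acquisition plus that frame's gridding plus the network
#' time, and no earlier than the previous completion plus the per-step
#' processing time (`step x t_grid + t_net`). Initialization delays the
#' first processing by `t_init_s`. The per-frame latency of a kept frame
#' is its block's completion minus the frame's acquisition start; the
#' backlog is the completion delay relative to steady state.
#'
#' @param model [timing_model()].
#' @param n_frames Stream length.
#' @param window,step Block schedule parameters.
#' @return List: `blocks` (completion_ms, backlog_ms per block), `frames`
#'   (frame, latency_ms for every kept frame), `steady_state_central_ms`,
#'   `steady_state_first_ms`.
#' @export
simulate_timing <- function(model, n_frames, window = 24, step = 18) {
  sch <- schedule_blocks(n_frames, window, step)
  fm <- model$frame_ms; tg <- model$t_grid_ms; tn <- model$t_net_ms
  n_b <- nrow(sch)
  comp <- numeric(n_b); backlog <- numeric(n_b)
  prev <- model$t_init_s * 1000
  for (b in seq_len(n_b)) {
    acq_end <- sch$end[b] * fm
    comp[b] <- max(acq_end + tg, prev + step * tg) + tn
    backlog[b] <- comp[b] - (acq_end + tg + tn)
    prev <- comp[b]
  }
  frames <- do.call(rbind, lapply(seq_len(n_b), function(b) {
    ks <- sch$kept_start[b]:(sch$kept_end[b] - 1L)
    data.frame(frame = ks, latency_ms = comp[b] - ks * fm)
  }))
  lead <- (window - step) %/% 2L
  central <- (window - (lead + step %/% 2L - 1L)) * fm + tg + tn
  first <- (window - lead) * fm + tg + tn
  list(blocks = data.frame(block = seq_len(n_b), completion_ms = comp,
                           backlog_ms = backlog),
       frames = frames,
       steady_state_central_ms = central,
       steady_state_first_ms = first)
}

#' Simulate a multi-coil real-time spiral acquisition of a phantom
#'
#' Velocity-encodes each cine frame (one-sided encoding), multiplies by
#' synthetic coil sensitivities, samples along the golden-angle trajectory
#' of the frame and adds complex Gaussian noise per coil.
#'
#' @param phantom Output of [generate_phantom()].
#' @param params [acq_params()] (its `voxel_mm` must match the phantom).
#' @param arm [design_vd_arm()] output.
#' @param phi0 Background phase: scalar, matrix, or [maxwell_model()].
#' @param seed Noise seed.
#' @return Object of class `rt_acquisition` with per-frame k-space for
#'   both encodings, the sampling (trajectories + weights), true coil
#'   maps, params and geometry.
#' @export
simulate_acquisition <- function(phantom, params, arm, phi0 = 0, seed = 1) {
  cine <- phantom$cine
  N <- dim(cine$mag)[1]; n_frames <- dim(cine$mag)[3]
  cfg <- phantom$truth$config
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  maps <- synth_coil_maps(cfg$n_coils, c(N, N), seed = seed)
  sampling <- make_frame_sampling(arm, params, n_frames)
  ph0 <- if (inherits(phi0, "maxwell_model")) maxwell_phase(phi0, c(N, N)) else phi0
  ns <- nrow(sampling[[1]]$traj$k)
  kc <- vector("list", n_frames); ke <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    pair <- encode_velocity(cine$mag[, , f], cine$vel[, , f], ph0,
                            cine$venc_cm_s)
    tr <- sampling[[f]]$traj
    mc <- matrix(0 + 0i, ns, cfg$n_coils); me <- mc
    for (c in seq_len(cfg$n_coils)) {
      mc[, c] <- nufft_sample(pair$comp * maps[, , c], tr$k, params$voxel_mm)
      me[, c] <- nufft_sample(pair$enc * maps[, , c], tr$k, params$voxel_mm)
    }
    if (cfg$noise_sd > 0) {
      sc <- cfg$noise_sd * mean(abs(mc))
      nz <- function(m) m + complex(real = stats::rnorm(length(m), 0, sc),
                                    imaginary = stats::rnorm(length(m), 0, sc))
      mc <- nz(mc); me <- nz(me)
    }
    kc[[f]] <- mc; ke[[f]] <- me
  }
  structure(list(kspace_comp = kc, kspace_enc = ke, sampling = sampling,
                 maps = maps, params = params, shape = c(N, N),
                 n_frames = n_frames, frame_ms = cine$frame_ms,
                 venc_cm_s = cine$venc_cm_s, noise_sd = cfg$noise_sd),
            class = "rt_acquisition")
}

#' Grid and coil-combine a whole acquisition into image series
#'
#' Initialization plus per-frame reconstruction: estimates coil maps from
#' the first `coil_map_frames` frames (flow-compensated encoding), then
#' grids every frame of both encodings, coil-combines and centre-crops.
#'
#' @param acq [simulate_acquisition()] output.
#' @param crop Spatial crop size.
#' @param maps Optional coil maps (skips estimation).
#' @param coil_map_frames Frames used for coil-map estimation.
#' @return List: `comp`, `enc` (complex `crop x crop x n_frames`), `maps`.
#' @export
grid_series <- function(acq, crop = 64, maps = NULL, coil_map_frames = 10) {
  N <- acq$shape[1]
  if (is.null(maps)) {
    nf <- min(coil_map_frames, acq$n_frames)
    first <- array(0 + 0i, dim = c(acq$shape, ncol(acq$kspace_comp[[1]]), nf))
    for (f in seq_len(nf)) first[, , , f] <- grid_frame_coils(acq, f, "comp")
    maps <- estimate_coil_maps(first)
  }
  y0 <- (N - crop) %/% 2L
  ys <- y0 + seq_len(crop)
  comp <- array(0 + 0i, dim = c(crop, crop, acq$n_frames))
  enc <- comp
  for (f in seq_len(acq$n_frames)) {
    comp[, , f] <- coil_combine(grid_frame_coils(acq, f, "comp"), maps)[ys, ys]
    enc[, , f] <- coil_combine(grid_frame_coils(acq, f, "enc"), maps)[ys, ys]
  }
  list(comp = comp, enc = enc, maps = maps)
}

grid_frame_coils <- function(acq, f, encoding = c("comp", "enc")) {
  encoding <- match.arg(encoding)
  ks <- if (encoding == "comp") acq$kspace_comp[[f]] else acq$kspace_enc[[f]]
  tr <- acq$sampling[[f]]$traj; w <- acq$sampling[[f]]$w
  n_coils <- ncol(ks)
  out <- array(0 + 0i, dim = c(acq$shape, n_coils))
  for (c in seq_len(n_coils))
    out[, , c] <- nufft_grid(ks[, c], w, tr$k, acq$params$voxel_mm, acq$shape)
  out
}

#' Run the full streaming reconstruction and monitoring pipeline
#'
#' Initialization estimates coil maps from the first 10 frames. Then per
#' scheduled block: grid both encodings for each coil, coil-combine,
#' centre-crop, normalize, deep-artifact-suppress both encodings, combine
#' into phase-contrast frames (optional polynomial background-phase
#' correction), CLAHE-prepare and segment, and convert kept frames' phase
#' to velocity. Finally the flow curve, beat detection and beat metrics
#' are computed over kept frames. A failing block is flagged and skipped.
#'
#' @param acq [simulate_acquisition()] output (or compatible structure).
#' @param suppressor Trained `suppressor`.
#' @param segmenter Trained `segmenter`.
#' @param crop Spatial crop passed to the networks.
#' @param window,step Sliding-window parameters (default 24/18).
#' @param maxwell Optional [maxwell_model()] on the cropped grid.
#' @param out_dir Optional output directory (flow/beat CSVs, JSON-lines
#'   monitoring records, NIfTI masks).
#' @param coil_map_frames Frames used for coil-map estimation.
#' @return List: `curve`, `peaks`, `beats`, `velocity`, `masks`, `prob`,
#'   `pc` (phase-contrast frames), `schedule`, `block_log`.
#' @export
run_pipeline <- function(acq, suppressor, segmenter, crop = 64,
                         window = 24, step = 18, maxwell = NULL,
                         out_dir = NULL, coil_map_frames = 10) {
  sch <- schedule_blocks(acq$n_frames, window, step)
  gs <- grid_series(acq, crop, coil_map_frames = coil_map_frames)
  maps <- gs$maps
  vel <- array(0, dim = c(crop, crop, acq$n_frames))
  msk <- array(FALSE, dim = c(crop, crop, acq$n_frames))
  prb <- array(0, dim = c(crop, crop, acq$n_frames))
  pc_out <- array(0 + 0i, dim = c(crop, crop, acq$n_frames))
  log <- data.frame(block = integer(), ok = logical(), note = character())
  for (b in seq_len(nrow(sch))) {
    res <- tryCatch({
      fr <- (sch$start[b] + 1L):sch$end[b]
      comp <- gs$comp[, , fr, drop = FALSE]
      enc <- gs$enc[, , fr, drop = FALSE]
      nb <- normalize_block(list(comp = comp, enc = enc,
                                 venc_cm_s = acq$venc_cm_s))
      rest <- suppress(suppressor, nb$pair)
      pc <- array(0 + 0i, dim = dim(comp))
      for (j in seq_along(fr))
        pc[, , j] <- combine_pair(list(comp = rest$comp[, , j],
                                       enc = rest$enc[, , j]), maxwell)
      seg_in <- seg_input(pc)
      sg <- segment(segmenter, seg_in)
      keep <- (sch$kept_start[b] + 1L):sch$kept_end[b]
      rel <- keep - sch$start[b]
      for (j in seq_along(keep)) {
        f <- keep[j]; r <- rel[j]
        vel[, , f] <- phase_to_velocity(Arg(pc[, , r]), acq$venc_cm_s)
        msk[, , f] <- sg$mask[, , r]
        prb[, , f] <- sg$prob[, , r]
        pc_out[, , f] <- pc[, , r] * nb$scale
      }
      TRUE
    }, error = function(e) conditionMessage(e))
    ok <- isTRUE(res)
    log <- rbind(log, data.frame(block = b, ok = ok,
                                 note = if (ok) "" else res))
  }
  vox <- acq$params$voxel_mm
  curve <- suppressWarnings(flow_curve(vel, msk, vox^2, acq$frame_ms))
  peaks <- tryCatch(detect_beats(curve), error = function(e) integer())
  beats <- if (length(peaks) >= 2) beat_metrics(curve, peaks) else NULL
  out <- list(curve = curve, peaks = peaks, beats = beats, velocity = vel,
              masks = msk, prob = prb, pc = pc_out, schedule = sch,
              block_log = log, maps = maps)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_beats_csv(res$curve, file.path(out_dir, "flow_curve.csv"))
  if (!is.null(res$beats)) {
    write_beats_csv(res$beats, file.path(out_dir, "beat_table.csv"))
    con <- file(file.path(out_dir, "monitor.jsonl"), "w")
    for (i in seq_len(nrow(res$beats)))
      writeLines(jsonlite::toJSON(as.list(res$beats[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
    close(con)
  }
  RNifti::writeNifti(array(as.integer(res$masks), dim = dim(res$masks)),
                     file.path(out_dir, "masks.nii.gz"))
  utils::write.csv(res$block_log, file.path(out_dir, "block_log.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
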