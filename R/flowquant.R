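# Flow quantification and beat-to-beat monitoring: flow curves from
# velocity maps and masks, systolic peak detection, and per-beat heart
# rate / stroke volume / cardiac output.

#' Flow curve from velocity maps and masks
#'
#' `q[t] = sum_mask v * pixel_area`, converting cm/s x mm^2 to mL/s
#' (factor 0.01).
#'
#' @param velocity Array `H x W x T` of through-plane velocity (cm/s).
#' @param masks Logical array of the same shape.
#' @param pixel_area_mm2 Pixel area in mm^2.
#' @param frame_ms Frame duration (ms); mid-frame times are
#'   `(t - 1/2) frame_ms`.
#' @return Object of class `flow_curve`: data frame `t_ms`, `q_ml_s`.
#' @export
flow_curve <- function(velocity, masks, pixel_area_mm2, frame_ms = 35.0) {
  stopifnot(all(dim(velocity) == dim(masks)))
  n <- dim(velocity)[3]
  q <- numeric(n)
  empty <- FALSE
  for (f in seq_len(n)) {
    m <- masks[, , f]
    if (!any(m)) { q[f] <- 0; empty <- TRUE }
    else q[f] <- sum(velocity[, , f][m]) * pixel_area_mm2 * 0.01
  }
  if (empty) warning("empty mask in at least one frame; flow set to 0 there")
  structure(data.frame(t_ms = (seq_len(n) - 0.5) * frame_ms, q_ml_s = q),
            class = c("flow_curve", "data.frame"))
}

#' Detect systolic peaks in a flow curve
#'
#' Local maxima subject to a minimum inter-peak distance of
#' `60000 / hr_max` ms and a prominence of at least `prom_frac` times the
#' running median of accepted peak heights (so detection is invariant to
#' curve scaling). Candidates are accepted greedily by height.
#'
#' @param curve [flow_curve()].
#' @param hr_max Maximum plausible heart rate (bpm); default 220.
#' @param prom_frac Prominence threshold as a fraction of the running
#'   median peak height.
#' @return Integer vector of peak frame indices (possibly empty).
#' @export
detect_beats <- function(curve, hr_max = 220, prom_frac = 0.2) {
  q <- curve$q_ml_s
  n <- length(q)
  dt <- if (n >= 2) diff(curve$t_ms[1:2]) else return(integer())
  if (n * dt < 2000) stop("need at least 2 s of data")
  min_dist <- max(1L, floor(60000 / hr_max / dt))
  cand <- which(diff(sign(diff(q))) < 0) + 1L
  if (!length(cand)) return(integer())
  prominence <- function(i) {
    lo <- max(1L, i - 3L * min_dist); hi <- min(n, i + 3L * min_dist)
    left <- min(q[lo:i]); right <- min(q[i:hi])
    q[i] - max(left, right)
  }
  cand <- cand[order(q[cand], decreasing = TRUE)]
  accepted <- integer()
  for (i in cand) {
    if (length(accepted) && any(abs(accepted - i) < min_dist)) next
    med <- if (length(accepted)) stats::median(q[accepted]) else q[i]
    if (prominence(i) >= prom_frac * med) accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' Beat-to-beat metrics from a flow curve and detected peaks
#'
#' Beats span peak to peak. Per beat: `SV` is the trapezoidal integral of
#' the flow curve (mL), `HR = 60000 / RR`, `CO = SV x HR / 1000`.
#'
#' @param curve [flow_curve()].
#' @param peaks Peak indices from [detect_beats()] (>= 2).
#' @return Object of class `beat_table`: data frame with `peak_time_ms`,
#'   `rr_ms`, `hr_bpm`, `sv_ml`, `co_l_min`, `flagged` (negative SV).
#' @export
beat_metrics <- function(curve, peaks) {
  stopifnot(length(peaks) >= 2)
  t <- curve$t_ms; q <- curve$q_ml_s
  out <- lapply(seq_len(length(peaks) - 1L), function(b) {
    i0 <- peaks[b]; i1 <- peaks[b + 1L]
    rr <- t[i1] - t[i0]
    idx <- i0:i1
    sv <- sum(diff(t[idx]) * (head(q[idx], -1) + tail(q[idx], -1)) / 2) / 1000
    hr <- 60000 / rr
    data.frame(peak_time_ms = t[i0], rr_ms = rr, hr_bpm = hr, sv_ml = sv,
               co_l_min = sv * hr / 1000, flagged = sv < 0)
  })
  out <- do.call(rbind, out)
  if (any(out$flagged))
    warning("negative stroke volume detected; check velocity sign convention")
  structure(out, class = c("beat_table", "data.frame"))
}

#' Running-median smoothing for display
#'
#' Edge-truncated running median over `window_beats` values; window 1 is
#' the identity. Agreement statistics should use unfiltered beats.
#'
#' @param series Numeric vector.
#' @param window_beats Window length (odd values behave symmetrically).
#' @return Smoothed vector of equal length.
#' @export
smooth_display <- function(series, window_beats = 5) {
  n <- length(series)
  if (window_beats <= 1 || n < window_beats) return(series)
  half <- window_beats %/% 2
  vapply(seq_len(n), function(i)
    stats::median(series[max(1, i - half):min(n, i + half)]), 0)
}

#' Write a beat table (or flow curve) to CSV
#'
#' @param x `beat_table` or `flow_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beats_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
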