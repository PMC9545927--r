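test_that("flow integration follows the unit chain exactly", {
  # 100 cm/s over 100 pixels of 2.1 mm -> 441 mL/s
  v <- array(0, c(20, 20, 1)); m <- array(FALSE, c(20, 20, 1))
  v[1:10, 1:10, 1] <- 100; m[1:10, 1:10, 1] <- TRUE
  expect_equal(flow_curve(v, m, 2.1^2)$q_ml_s, 441)
  expect_equal(flow_curve(v * 0, m, 2.1^2)$q_ml_s, 0)
  expect_warning(flow_curve(v, m & FALSE, 2.1^2), "empty")
  # scaling chain: x2 velocity, x2 flow (dimensional consistency)
  expect_equal(flow_curve(2 * v, m, 2.1^2)$q_ml_s,
               2 * flow_curve(v, m, 2.1^2)$q_ml_s)
})

test_that("discretized parabolic flow approaches pi R^2 v_peak / 2", {
  vox <- 1.0; R <- 15; vpk <- 120
  N <- 64; yy <- outer(1:N, rep(1, N)); xx <- t(yy)
  d2 <- (yy - N / 2)^2 + (xx - N / 2)^2
  mask <- d2 <= R^2
  v <- matrix(0, N, N); v[mask] <- vpk * (1 - d2[mask] / R^2)
  q <- flow_curve(array(v, c(N, N, 1)), array(mask, c(N, N, 1)), vox^2)$q_ml_s
  expect_equal(q, pi * R^2 * vpk / 2 * 0.01, tolerance = 0.05)
  expect_equal(pi * R^2 * vpk / 2 * 0.01, 424.1, tolerance = 1e-3)
})

test_that("beat detection finds every phantom beat and ignores flats", {
  ph <- fix_phantom_small()   # 4 s at HR 75: 5 beats
  cr <- flow_curve(ph$truth$velocity, ph$truth$masks, 2.1^2, 35)
  pk <- detect_beats(cr)
  n_complete <- sum(ph$truth$beats$peak_time_ms < max(cr$t_ms))
  expect_equal(length(pk), n_complete)
  # RR intervals equal the configured rhythm
  bm <- beat_metrics(cr, pk)
  expect_equal(mean(bm$rr_ms), 800, tolerance = 0.05)
  # scale invariance
  cr2 <- cr; cr2$q_ml_s <- cr2$q_ml_s * 2
  expect_identical(detect_beats(cr2), pk)
  # constant curve: no peaks
  flat <- cr; flat$q_ml_s <- rep(5, nrow(flat))
  expect_length(detect_beats(flat), 0)
  short <- cr[1:20, ]
  expect_error(detect_beats(short), "2 s")
})

test_that("beat metrics arithmetic and volume conservation", {
  t_ms <- (1:200 - 0.5) * 40
  q <- 100 + 80 * sin(2 * pi * (t_ms - 10) / 800)
  cr <- structure(data.frame(t_ms = t_ms, q_ml_s = q),
                  class = c("flow_curve", "data.frame"))
  pk <- detect_beats(cr)
  bm <- beat_metrics(cr, pk)
  expect_equal(bm$hr_bpm, 60000 / bm$rr_ms)
  expect_equal(bm$co_l_min, bm$sv_ml * bm$hr_bpm / 1000)
  # peak-to-peak segmentation conserves total volume
  total <- sum(diff(cr$t_ms[pk[1]:pk[length(pk)]]) *
                 (head(q[pk[1]:pk[length(pk)]], -1) +
                  tail(q[pk[1]:pk[length(pk)]], -1)) / 2) / 1000
  expect_equal(sum(bm$sv_ml), total, tolerance = 1e-9)
  # RR 800 ms -> 75 bpm; SV 80 at 75 bpm -> CO 6
  expect_equal(unique(round(bm$hr_bpm, 6)), 75)
  expect_equal(0.08 * 75, 6)
})

test_that("running-median display filter", {
  expect_equal(smooth_display(rep(3, 10)), rep(3, 10))
  s <- c(5, 5, 50, 5, 5, 5, 5)
  expect_equal(smooth_display(s)[3], 5)
  expect_identical(smooth_display(s, 1), s)
})
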