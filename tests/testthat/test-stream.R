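test_that("block schedule reproduces the 24/18 worked example", {
  s <- schedule_blocks(60)
  expect_equal(s$start, c(0, 18, 36))
  expect_equal(s$end, c(24, 42, 60))
  expect_equal(s$kept_start, c(0, 21, 39))
  expect_equal(s$kept_end, c(21, 39, 60))
  s1 <- schedule_blocks(24)
  expect_equal(nrow(s1), 1)
  expect_equal(c(s1$kept_start, s1$kept_end), c(0, 24))
  expect_error(schedule_blocks(23), "window")
})

test_that("kept frames partition any stream length exactly once", {
  for (n in c(24:30, 41:43, 59:61, 100, 137, 5143)) {
    s <- schedule_blocks(n)
    kept <- unlist(lapply(seq_len(nrow(s)), function(i)
      s$kept_start[i]:(s$kept_end[i] - 1L)))
    expect_identical(sort(kept), 0:(n - 1L))
    expect_equal(length(kept), n)     # no duplicates
    expect_true(all(s$kept_start >= s$start & s$kept_end <= s$end))
    expect_true(all(s$end - s$start == 24))
  }
  # 18 kept frames per steady-state step = 630 ms of acquisition
  expect_equal(18 * 35, 630)
})

test_that("pair normalization is scale-invariant and phase-preserving", {
  set.seed(71)
  pair <- list(comp = rand_cx_block(16, 16, 3, 0.2),
               enc = rand_cx_block(16, 16, 3, 0.2), venc_cm_s = 200)
  nb <- normalize_block(pair)
  nb10 <- normalize_block(list(comp = 10 * pair$comp, enc = 10 * pair$enc,
                               venc_cm_s = 200))
  expect_equal(nb$pair$comp, nb10$pair$comp, tolerance = 1e-12)
  expect_equal(nb10$scale, 10 * nb$scale)
  # inverse mapping restores inputs (away from the clipped 1% tail)
  restored <- nb$pair$comp * nb$scale
  keep <- abs(Re(pair$comp)) < nb$scale & abs(Im(pair$comp)) < nb$scale &
    abs(Re(pair$enc)) < nb$scale & abs(Im(pair$enc)) < nb$scale
  expect_equal(restored[keep], pair$comp[keep], tolerance = 1e-6)
  # shared scale: phase difference (velocity) unaffected where unclipped
  expect_equal(Arg(nb$pair$enc * Conj(nb$pair$comp))[keep],
               Arg(pair$enc * Conj(pair$comp))[keep], tolerance = 1e-9)
  expect_error(normalize_block(list(comp = array(0i, c(4, 4, 1)),
                                    enc = array(0i, c(4, 4, 1)))),
               "degenerate")
})

test_that("timing model reproduces the published latency arithmetic", {
  tm <- timing_model()
  sim <- simulate_timing(tm, 5143)
  expect_equal(sim$steady_state_central_ms, 622.2)
  expect_equal(sim$steady_state_first_ms, 902.2)
  # per-frame trace: in steady state the central kept frame of a block
  # (block-relative index 11) has that same latency
  st <- sim$frames[sim$frames$frame == 18 * 250 + 3 + 8, ]
  expect_equal(st$latency_ms, 622.2, tolerance = 1e-9)
  # initialization backlog drains: 18 x 16.2 + 151 = 443 < 630 per step
  # (the final block is pinned to the stream end and sits closer than one
  # full step to its predecessor, so it is excluded)
  nb_ <- nrow(sim$blocks)
  expect_true(all(diff(sim$blocks$backlog_ms[2:(nb_ - 1)]) <= 1e-9))
  expect_lt(sim$blocks$backlog_ms[nb_ - 1], 1)
  # without initialization there is no backlog at all
  sim0 <- simulate_timing(timing_model(t_init_s = 0), 240)
  expect_true(all(abs(sim0$blocks$backlog_ms) < 1e-9))
})
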