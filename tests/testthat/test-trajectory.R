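test_that("variable-density arm matches the independent pitch quadrature", {
  p <- fix_params(); s <- density_spec()
  arm <- fix_arm()
  # independent oracle: turns = fov * k_max * integral of d(rho)/R(rho)
  Rfun <- function(rho) ifelse(rho <= 0.2, 26,
                        ifelse(rho >= 0.9, 65, 26 + 39 * (rho - 0.2) / 0.7))
  turns_expected <- p$fov_mm * p$k_max *
    integrate(function(r) 1 / Rfun(r), 0, 1, rel.tol = 1e-10)$value
  expect_equal(arm$turns, turns_expected, tolerance = 1e-3)
  expect_equal(turns_expected, 2.445, tolerance = 1e-3)
  # forced geometry
  expect_equal(max(sqrt(rowSums(arm$k^2))), 1 / (2 * 2.1), tolerance = 1e-9)
  expect_equal(arm$k[1, ], c(kx = 0, ky = 0))
  expect_true(all(diff(arm$r) > -1e-12))
})

test_that("constant-density limit is an Archimedean spiral of uniform pitch", {
  p <- fix_params()
  s <- density_spec(arm_accel_inner = 26, arm_accel_outer = 26)
  arm <- design_vd_arm(p, s, 1024)
  aud <- acceleration_audit(arm, p, arms_per_frame = 1)
  expect_equal(aud$per_arm_inner, 26, tolerance = 0.01)
  expect_equal(aud$per_arm_outer, 26, tolerance = 0.01)
  gaps <- aud$crossings$gap_x_fov
  expect_lt(max(abs(gaps - 26)) / 26, 0.02)
})

test_that("acceleration audit reproduces the printed design within 5%", {
  aud <- acceleration_audit(fix_arm())
  expect_equal(aud$per_arm_inner, 26, tolerance = 0.05)
  expect_equal(aud$per_arm_outer, 65, tolerance = 0.05)
  expect_equal(aud$per_frame_inner, 8.7, tolerance = 0.05)
  expect_equal(aud$per_frame_outer, 21.7, tolerance = 0.05)
  expect_equal(aud$density_ratio, 2.5, tolerance = 0.05)
})

test_that("invalid density specifications are rejected", {
  expect_error(density_spec(r_inner_frac = 0.9, r_outer_frac = 0.2), "invalid")
  expect_error(density_spec(arm_accel_inner = 65, arm_accel_outer = 26),
               "invalid")
  expect_error(density_spec(r_inner_frac = 0), "invalid")
})

test_that("golden-angle schedule is deterministic, stateless, repeat-free", {
  a100 <- golden_angle_schedule(100)
  expect_identical(a100[1], 0)
  expect_identical(golden_angle_schedule(40), a100[1:40])
  # closed form with the 137.51-degree convention
  ga_small <- 2 * pi * (1 - 1 / ((1 + sqrt(5)) / 2))
  expect_equal(golden_angle_schedule(2, ga = ga_small)[2], 2.39996,
               tolerance = 1e-5)
  # irrationality: no two angles coincide at float precision
  expect_equal(length(unique(round(a100, 10))), 100)
})

test_that("frame trajectories continue the golden-angle arm sequence", {
  arm <- fix_arm()
  tr0 <- frame_trajectory(arm, 0)
  tr1 <- frame_trajectory(arm, 1)
  sched <- golden_angle_schedule(6)
  expect_equal(tr0$arm_angles, sched[1:3])
  expect_equal(tr1$arm_angles, sched[4:6])
  expect_length(tr0$arm_angles, 3)
  expect_equal(nrow(tr0$k), 3 * arm$n_samples)
  expect_true(all(tr0$arm_angles >= 0 & tr0$arm_angles < 2 * pi))
})

test_that("scan frame-count arithmetic matches the protocol", {
  expect_identical(frames_for_duration(180, 35), 5143L)
})
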