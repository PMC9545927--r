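test_that("synthetic coil maps are RSS-normalized and reproducible", {
  expect_equal(synth_coil_maps(1, c(16, 16)), array(1 + 0i, c(16, 16, 1)))
  m <- synth_coil_maps(4, c(24, 24), seed = 2)
  rss <- sqrt(apply(abs(m)^2, c(1, 2), sum))
  expect_equal(max(abs(rss - 1)), 0, tolerance = 1e-9)
  expect_identical(m, synth_coil_maps(4, c(24, 24), seed = 2))
})

test_that("coil-map estimation recovers synthetic maps", {
  set.seed(21)
  maps <- synth_coil_maps(4, c(32, 32), seed = 5)
  obj <- matrix(0, 32, 32); obj[9:24, 9:24] <- 1
  frames <- array(0 + 0i, c(32, 32, 4, 6))
  for (f in 1:6) for (c in 1:4)
    frames[, , c, f] <- obj * maps[, , c] *
      (1 + 0.05 * rand_cx_mat(32, sd = 1))
  est <- estimate_coil_maps(frames)
  sup <- obj > 0
  for (c in 1:4)
    expect_gt(cor(abs(est[, , c][sup]), abs(maps[, , c][sup])), 0.95)
  # single coil: unit magnitude in support
  est1 <- estimate_coil_maps(array(frames[, , 1, , drop = FALSE],
                                   c(32, 32, 1, 6)))
  expect_equal(mean(abs(est1[, , 1][sup])), 1, tolerance = 1e-6)
  # averaging idempotence: identical frames give the single-frame answer
  rep10 <- array(rep(frames[, , , 1], 10), c(32, 32, 4, 10))
  expect_equal(estimate_coil_maps(rep10),
               estimate_coil_maps(array(frames[, , , 1], c(32, 32, 4, 1))))
  expect_error(estimate_coil_maps(array(0 + 0i, c(8, 8, 2, 1))), "degenerate")
})

test_that("conjugate coil combination inverts map-weighted images", {
  set.seed(22)
  maps <- synth_coil_maps(3, c(16, 16), seed = 7)
  x <- rand_cx_mat(16)
  imgs <- array(0 + 0i, c(16, 16, 3))
  for (c in 1:3) imgs[, , c] <- maps[, , c] * x
  expect_equal(coil_combine(imgs, maps), x, tolerance = 1e-12)
  one <- array(1 + 0i, c(16, 16, 1))
  expect_equal(coil_combine(array(x, c(16, 16, 1)), one), x)
  y <- rand_cx_mat(16)
  imgs2 <- imgs; for (c in 1:3) imgs2[, , c] <- imgs2[, , c] + maps[, , c] * y
  expect_equal(coil_combine(imgs2, maps),
               coil_combine(imgs, maps) + y, tolerance = 1e-12)
})

test_that("velocity encoding follows the one-sided phase convention", {
  mag <- matrix(1, 4, 4)
  pair <- encode_velocity(mag, matrix(100, 4, 4), 0, 200)
  expect_equal(Arg(pair$enc[1, 1]), pi / 2)
  p0 <- encode_velocity(mag, matrix(0, 4, 4), 0.3, 200)
  expect_equal(p0$enc, p0$comp)
  expect_error(encode_velocity(mag, mag, 0, -1), "venc")
  # beyond-VENC velocities alias
  pw <- encode_velocity(mag, matrix(250, 4, 4), 0, 200)
  v <- phase_to_velocity(Arg(pw$enc * Conj(pw$comp)), 200)
  expect_equal(v[1, 1], -150)
})

test_that("encode -> combine -> decode is exact under arbitrary phi0 and coils", {
  set.seed(23)
  venc <- 200
  maps <- synth_coil_maps(3, c(12, 12), seed = 9)
  for (rep in 1:5) {
    mag <- matrix(runif(144, 0.2, 1), 12)
    vel <- matrix(runif(144, -150, 150), 12)
    phi0 <- matrix(runif(144, -6, 6), 12)    # beyond +/- pi: wrap safety
    pair <- encode_velocity(mag, vel, phi0, venc)
    # through coil weighting and conjugate combination
    cc <- function(z) {
      imgs <- array(0 + 0i, c(12, 12, 3))
      for (c in 1:3) imgs[, , c] <- maps[, , c] * z
      coil_combine(imgs, maps)
    }
    pc <- combine_pair(list(comp = cc(pair$comp), enc = cc(pair$enc)))
    expect_equal(phase_to_velocity(Arg(pc), venc), vel, tolerance = 1e-9)
    expect_equal(abs(pc), mag, tolerance = 1e-9)
    # adding 2 pi to the background phase changes nothing
    pair2 <- encode_velocity(mag, vel, phi0 + 2 * pi, venc)
    pc2 <- combine_pair(pair2)
    expect_equal(phase_to_velocity(Arg(pc2), venc), vel, tolerance = 1e-9)
  }
})

test_that("polynomial background phase is removed by the Maxwell slot", {
  cf <- matrix(0, 3, 3)
  cf[1, 1] <- 0.3; cf[2, 1] <- -0.4; cf[1, 2] <- 0.2
  cf[3, 1] <- 0.15; cf[1, 3] <- -0.25; cf[2, 2] <- 0.1
  mw <- maxwell_model(cf)
  ph <- maxwell_phase(mw, c(20, 20))
  mag <- matrix(1, 20, 20); vel <- matrix(40, 20, 20)
  pair <- encode_velocity(mag, vel, 0, 200)
  pair$enc <- pair$enc * exp(1i * ph)   # background phase on the difference
  pc <- combine_pair(pair, maxwell = mw)
  expect_lt(max(abs(Arg(pc) - pi * 40 / 200)), 1e-6)
  expect_error(maxwell_model(matrix(1, 3, 3)), "degree")
})

test_that("phase/velocity conversion round-trips inside VENC", {
  expect_equal(phase_to_velocity(pi / 2, 200), 100)
  expect_equal(phase_to_velocity(0, 200), 0)
  v <- seq(-199, 199, by = 7)
  expect_equal(phase_to_velocity(velocity_to_phase(v, 200), 200), v)
})
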