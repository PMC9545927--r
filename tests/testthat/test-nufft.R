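test_that("forward NUFFT agrees with brute-force DFT summation", {
  set.seed(11)
  voxel <- 2
  img <- rand_cx_mat(8)
  kmax <- 1 / (2 * voxel)
  k <- cbind(runif(50, -kmax, kmax), runif(50, -kmax, kmax))
  s <- nufft_sample(img, k, voxel)
  s0 <- ndft_oracle(img, k, voxel)
  expect_lt(max(abs(s - s0)) / max(abs(s0)), 1e-6)
})

test_that("forward/adjoint pairs satisfy the inner-product identity", {
  set.seed(12)
  voxel <- 1.5
  kmax <- 1 / (2 * voxel)
  for (rep in 1:5) {
    img <- rand_cx_mat(8)
    k <- cbind(runif(30, -kmax, kmax), runif(30, -kmax, kmax))
    y <- complex(real = rnorm(30), imaginary = rnorm(30))
    lhs <- sum(nufft_sample(img, k, voxel) * Conj(y))
    rhs <- sum(img * Conj(nufft_grid(y, NULL, k, voxel, c(8, 8))))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("unnormalized convention and degenerate inputs behave as specified", {
  voxel <- 2
  img <- matrix(3 + 0i, 8, 8)
  expect_equal(nufft_sample(img, matrix(0, 1, 2), voxel)[1], 3 * 64 + 0i,
               tolerance = 1e-6)
  # off-centre delta: modulus constant over k
  d <- matrix(0 + 0i, 8, 8); d[3, 6] <- 1
  set.seed(13)
  k <- cbind(runif(20, -0.25, 0.25), runif(20, -0.25, 0.25))
  expect_lt(diff(range(abs(nufft_sample(d, k, voxel)))), 1e-6)
  # zero samples grid to a zero image
  z <- nufft_grid(complex(real = numeric(4)), NULL, matrix(0.1, 4, 2), voxel,
                  c(8, 8))
  expect_equal(max(abs(z)), 0)
  expect_error(nufft_sample(img, matrix(c(0.3, 0), 1, 2), voxel),
               "out-of-band")
  expect_error(nufft_grid(complex(real = 1:3), rep(1, 4), matrix(0, 3, 2),
                          voxel, c(8, 8)), "weights")
})

test_that("density weights: scale rules, positivity, radial law, quality", {
  p <- fix_params()
  # single sample normalizes to the configured total
  single <- list(k = matrix(0, 1, 2))
  expect_equal(density_compensation(single, p, total = 2.5), 2.5)
  # printed trajectory: finite, non-negative
  tr <- fix_frame0()
  w <- density_compensation(tr, p)
  expect_true(all(is.finite(w)) && all(w >= 0))
  # uniform-pitch spiral sampled uniformly in angle: iterative weights
  # approximately proportional to |k| away from the centre
  kmax <- p$k_max
  th <- seq(0, 120 * pi, length.out = 24000)   # gaps within kernel reach
  r <- kmax * th / max(th)
  traj_u <- list(k = cbind(r * cos(th), r * sin(th)))
  wu <- density_compensation(traj_u, p, method = "pipe", calibrate = FALSE)
  sel <- r > 0.1 * kmax & r < 0.95 * kmax
  ratio <- wu[sel] / r[sel]
  expect_lt(stats::sd(ratio) / mean(ratio), 0.1)
})

test_that("gridding quality: dense spiral near-exact, printed design bounded", {
  p <- fix_params()
  N <- 64; vox <- p$fov_mm / N
  pd <- acq_params(fov_mm = p$fov_mm, voxel_mm = vox)
  yy <- outer(((1:N) - N / 2 - 0.5)^2, rep(1, N))
  g <- exp(-(yy + t(yy)) / (2 * (N / 6)^2))
  # fully sampled control: uniform unit-pitch spiral
  sd_ <- density_spec(arm_accel_inner = 1, arm_accel_outer = 1.0001)
  armd <- design_vd_arm(pd, sd_, 8192)
  trd <- frame_trajectory(armd, 0, pd)
  wd <- density_compensation(trd, pd)
  recd <- grid_samples(nufft_sample(g + 0i, trd$k, vox), wd, trd, c(N, N), vox)
  expect_lt(sqrt(sum(abs(recd - g)^2) / sum(g^2)), 0.05)
  # printed 8.7/21.7-fold undersampled design: aliasing-dominated
  # regression bound (adjoint recon cannot do better at this acceleration)
  tr <- fix_frame0()
  w <- density_compensation(tr, p)
  N2 <- 192
  yy2 <- outer(((1:N2) - N2 / 2 - 0.5)^2, rep(1, N2))
  g2 <- exp(-(yy2 + t(yy2)) / (2 * 48^2))
  rec <- grid_samples(nufft_sample(g2 + 0i, tr$k, 2.1), w, tr, c(N2, N2), 2.1)
  expect_lt(sqrt(sum(abs(rec - g2)^2) / sum(g2^2)), 0.65)
})
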