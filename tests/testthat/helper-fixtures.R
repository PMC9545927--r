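# Shared fixtures, memoized so expensive geometry is built once per run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# printed-protocol geometry (400 mm FOV, 2.1 mm voxel)
fix_params <- function() acq_params()

fix_arm <- function(n = 2048) {
  memo(paste0("arm", n), function()
    design_vd_arm(acq_params(), density_spec(), n))
}

fix_frame0 <- function() {
  memo("frame0", function() frame_trajectory(fix_arm(), 0))
}

# small-grid geometry used by phantom-scale tests (96 px at 2.1 mm)
fix_params_small <- function() acq_params(fov_mm = 96 * 2.1, voxel_mm = 2.1)

fix_arm_small <- function() {
  memo("arm_small", function()
    design_vd_arm(fix_params_small(), density_spec(), 1024))
}

rand_cx_mat <- function(H, W = H, sd = 1) {
  matrix(complex(real = rnorm(H * W, 0, sd), imaginary = rnorm(H * W, 0, sd)),
         H, W)
}

rand_cx_block <- function(H, W, T, sd = 0.3) {
  array(complex(real = rnorm(H * W * T, 0, sd),
                imaginary = rnorm(H * W * T, 0, sd)), c(H, W, T))
}

# brute-force 2D NDFT oracle: sum_x img(x) exp(-2 pi i k . r), r in mm
ndft_oracle <- function(img, k, voxel_mm) {
  H <- nrow(img); W <- ncol(img)
  ty <- ((0:(H - 1)) - H %/% 2) * voxel_mm
  tx <- ((0:(W - 1)) - W %/% 2) * voxel_mm
  vapply(seq_len(nrow(k)), function(j) {
    ph <- outer(ty * k[j, 2], tx * k[j, 1], "+")
    sum(img * exp(-2i * pi * ph))
  }, complex(1))
}

# independent windowed-loop SSIM oracle (11x11 Gaussian, sigma 1.5,
# valid interior) -- deliberately naive, no shared code with the package
ssim_oracle <- function(x, y, data_range = 1) {
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  g <- outer(dnorm(-5:5, 0, 1.5), dnorm(-5:5, 0, 1.5))
  g <- g / sum(g)
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (cy in 6:(H - 5)) for (cx in 6:(W - 5)) {
    wx <- x[(cy - 5):(cy + 5), (cx - 5):(cx + 5)]
    wy <- y[(cy - 5):(cy + 5), (cx - 5):(cx + 5)]
    mx <- sum(g * wx); my <- sum(g * wy)
    vx <- sum(g * wx^2) - mx^2; vy <- sum(g * wy^2) - my^2
    cxy <- sum(g * wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# tiny phantom used across several test files
fix_phantom_small <- function() {
  memo("phantom_small", function()
    generate_phantom(phantom_config(grid = 64, duration_s = 4, hr_bpm = 75,
                                    sv_ml = 80, radius_mm = 15,
                                    vessel_center = c(0.5, 0.5),
                                    motion_amp_px = 0, noise_sd = 0,
                                    resp_sv_frac = 0, rr_jitter_sd = 0,
                                    seed = 3)))
}
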