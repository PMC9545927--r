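test_that("block packaging: counts, crop geometry, shared scale", {
  set.seed(31)
  co <- rand_cx_block(192, 192, 48); tr <- rand_cx_block(192, 192, 48)
  blocks <- make_blocks(co, tr, block = 24, crop = 128)
  expect_length(blocks, 2)
  expect_equal(dim(blocks[[1]]$corrupted), c(128, 128, 24))
  # centre crop of a 192 grid keeps rows/cols 33..160 (1-based)
  marker <- array(0 + 0i, c(192, 192, 24)); marker[33, 160, 1] <- 5
  mb <- make_blocks(marker, marker, 24, 128)[[1]]
  expect_equal(abs(mb$truth[1, 128, 1]) > 0, TRUE)
  expect_equal(sum(abs(mb$truth) > 0), 1)
  # same scale applied to both members
  b <- blocks[[1]]
  expect_equal(b$corrupted * b$meta$scale, co[33:160, 33:160, 1:24])
  expect_warning(out <- make_blocks(co[, , 1:23], tr[, , 1:23], 24, 128),
                 "skipped")
  expect_length(out, 0)
})

test_that("augmentation applies one transform to both members and the mask", {
  set.seed(32)
  pr <- training_pair(rand_cx_block(16, 16, 4), rand_cx_block(16, 16, 4))
  mask <- array(runif(16 * 16 * 4) > 0.7, c(16, 16, 4))
  out <- augment_pair(pr, p_translate = 1, mask = mask)
  # phase offsets leave magnitudes untouched; geometry only permutes them
  expect_equal(sort(round(abs(out$corrupted), 12)),
               sort(round(abs(pr$corrupted), 12)))
  # alignment: the truth/corrupted difference field is permuted the same way
  expect_equal(sort(round(abs(out$truth - out$corrupted), 10)),
               sort(round(abs(pr$truth - pr$corrupted), 10)))
  expect_equal(sum(out$meta$mask), sum(mask))
  # phase-offset magnitude bounded by pi/2: encode a constant-1 pair
  one <- training_pair(array(1 + 0i, c(16, 16, 2)), array(1 + 0i, c(16, 16, 2)))
  o2 <- augment_pair(one, p_translate = 0)
  expect_lte(max(abs(Arg(o2$truth))), pi / 2 + 1e-9)
})

test_that("translation augmentation frequency matches its probability", {
  set.seed(33)
  pr <- training_pair(rand_cx_block(12, 12, 2), rand_cx_block(12, 12, 2))
  hits <- vapply(1:4000, function(i)
    augment_pair(pr, p_translate = 0.5)$meta$augment$translated, TRUE)
  expect_equal(mean(hits), 0.5, tolerance = 0.03)
})

test_that("synthetic undersampling: dense limit clean, printed design aliased", {
  ph <- fix_phantom_small()
  cx <- cine_complex(ph$cine)[, , 1:2, drop = FALSE]
  p <- acq_params(fov_mm = 64 * 2.1, voxel_mm = 2.1)
  nrm <- function(a) pmin(abs(a) / quantile(abs(a), 0.99), 1)
  # near-Nyquist uniform spiral on a bandlimited (blurred) cine:
  # output ~ input; the iterative density estimator is the right choice
  # when gaps are within its kernel's reach
  kern <- rtflow:::gauss_kernel_1d(4)
  sm <- cx
  for (f in 1:2) sm[, , f] <- cpp_gauss_blur2(Re(cx[, , f]), kern) +
    1i * cpp_gauss_blur2(Im(cx[, , f]), kern)
  sd_ <- density_spec(arm_accel_inner = 1, arm_accel_outer = 1.0001)
  armd <- design_vd_arm(p, sd_, 8192)
  smpd <- make_frame_sampling(armd, p, 2, method = "pipe")
  ald <- synth_undersample(sm, smpd, 2.1)
  expect_gt(ssim2d(nrm(ald[, , 1]), nrm(sm[, , 1])), 0.98)
  # the prescribed acceleration visibly corrupts the frames
  arm <- design_vd_arm(p, density_spec(), 1024)
  smp <- make_frame_sampling(arm, p, 2)
  al <- synth_undersample(cx, smp, 2.1)
  expect_lt(ssim2d(nrm(al[, , 1]), nrm(cx[, , 1])), 0.95)
  # zero in, zero out
  z <- synth_undersample(array(0 + 0i, c(64, 64, 1)), smp, 2.1)
  expect_equal(max(abs(z)), 0)
})

test_that("train/val/test split is disjoint and sized like the cohort design", {
  sp <- split_ids(sprintf("case%03d", 1:516), 470, 30, 16)
  expect_length(sp$train, 470); expect_length(sp$val, 30)
  expect_length(sp$test, 16)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
})
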