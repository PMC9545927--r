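test_that("network shapes, parameter scaling, and identity initialization", {
  # single-scale model: plain conv stack preserving shape
  m1 <- build_unet(unet_spec(1, 4, 1), seed = 1)
  X <- matrix(rnorm(8 * 8 * 4 * 2), ncol = 2)
  Y <- unet_forward(m1, X, c(4L, 8L, 8L))
  expect_equal(dim(Y), dim(X))
  # two-scale model on a 24-frame block
  m2 <- build_unet(unet_spec(2, 8, 1), seed = 1)
  blk <- rand_cx_block(16, 16, 4)
  bm <- block_to_mat(blk)
  out <- mat_to_block(unet_forward(m2, bm$X, bm$dims), bm$dims)
  expect_equal(dim(out), dim(blk))
  # residual + zero-initialized head: fresh model is the identity
  expect_equal(out, blk, tolerance = 1e-12)
  # doubling the filter count roughly quadruples the parameter count
  pa <- build_unet(unet_spec(2, 8, 1), seed = 1)$n_params
  pb <- build_unet(unet_spec(2, 16, 1), seed = 1)$n_params
  expect_gt(pb / pa, 3.4); expect_lt(pb / pa, 4.3)
  expect_error(unet_forward(m2, X, c(4L, 7L, 8L)), "divisible")
})

test_that("U-Net backprop matches finite differences", {
  set.seed(51)
  m <- build_unet(unet_spec(2, 4, 1), seed = 2)
  m$head$W <- matrix(rnorm(length(m$head$W), 0, 0.3), nrow(m$head$W))
  dims <- c(4L, 8L, 8L); N <- prod(dims)
  X <- matrix(rnorm(N * 2), N, 2)
  tgt <- matrix(rnorm(N * 2), N, 2)
  fw <- unet_forward(m, X, dims, cache = TRUE)
  g <- rtflow:::unet_backward(m, fw$Y - tgt, fw$cache)
  loss <- function(mm) sum((unet_forward(mm, X, dims) - tgt)^2) / 2
  base <- loss(m); e <- 1e-6
  probes <- list(
    list(\(mm, v) { mm$enc[[1]][[1]]$W[5, 2] <- v; mm },
         \(mm) mm$enc[[1]][[1]]$W[5, 2], g$enc[[1]][[1]]$dW[5, 2]),
    list(\(mm, v) { mm$dec[[1]][[2]]$W[30, 1] <- v; mm },
         \(mm) mm$dec[[1]][[2]]$W[30, 1], g$dec[[1]][[2]]$dW[30, 1]),
    list(\(mm, v) { mm$enc[[2]][[1]]$b[3] <- v; mm },
         \(mm) mm$enc[[2]][[1]]$b[3], g$enc[[2]][[1]]$db[3]))
  for (p in probes) {
    fd <- (loss(p[[1]](m, p[[2]](m) + e)) - base) / e
    expect_equal(fd, p[[3]], tolerance = 1e-4)
  }
})

test_that("smoke training decreases loss and stays finite", {
  set.seed(52)
  truth <- rand_cx_block(16, 16, 4, sd = 0.3)
  pairs <- lapply(1:2, function(i)
    training_pair(truth + rand_cx_block(16, 16, 4, sd = 0.2), truth))
  sup <- train_suppressor(pairs, unet_spec(2, 4, 1, lr = 2e-3), epochs = 3,
                          seed = 4, val_pairs = pairs[1])
  expect_true(all(is.finite(sup$history$train_loss)))
  expect_lt(sup$history$train_loss[3], sup$history$train_loss[1])
  # suppression is stateless: same output twice
  r1 <- suppress(sup, pairs[[1]]$corrupted)
  r2 <- suppress(sup, pairs[[1]]$corrupted)
  expect_identical(r1, r2)
  # encoding-pair blocks pass each member independently
  pb <- suppress(sup, list(comp = pairs[[1]]$corrupted,
                           enc = pairs[[2]]$corrupted))
  expect_identical(pb$comp, r1)
})

test_that("successive halving follows the 9 -> 3 -> 1 schedule within budget", {
  space <- lapply(1:9, function(i) unet_spec(1, 4 + i, 1, lr = 1e-3))
  planted <- vapply(space, function(s) abs(s$init_filters - 9), 0)  # best: #4
  calls <- new.env(); calls$n <- 0
  res <- successive_halving_search(space, budget = 60,
    eval_fn = function(spec, epochs) {
      calls$n <- calls$n + epochs
      planted[vapply(space, identical, TRUE, y = spec)]
    })
  expect_equal(res$best$init_filters, 9)
  expect_equal(unique(table(res$trace$round)), c(9, 3, 1),
               ignore_attr = TRUE)
  expect_lte(res$epochs_used, 60)
  expect_equal(calls$n, res$epochs_used)
})
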