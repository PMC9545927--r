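# Optional compressed-sensing oracle: temporal-total-variation regularized
# reconstruction of a multi-frame k-space block by monotone accelerated
# proximal-gradient descent (smoothed TV gradient, FISTA-style momentum
# with restart and backtracking so the objective never increases).

#' Compressed-sensing configuration
#'
#' @param lambda_t Temporal-TV weight (default 5e-4, on unit-normalized data).
#' @param n_iters Iterations (default 40).
#' @param step Initial gradient step (estimated from the operator norm if NULL).
#' @param tv_eps Charbonnier smoothing of the TV magnitude.
#' @return Object of class `cs_config`.
#' @export
cs_config <- function(lambda_t = 5e-4, n_iters = 40, step = NULL,
                      tv_eps = 1e-6) {
  stopifnot(lambda_t > 0, n_iters >= 1)
  structure(list(lambda_t = lambda_t, n_iters = n_iters, step = step,
                 tv_eps = tv_eps), class = "cs_config")
}

#' Temporal-TV compressed-sensing reconstruction of a frame block
#'
#' Minimizes `sum_f ||F_f x_f - y_f||^2 + lambda sum |x_{f+1} - x_f|`
#' (Charbonnier-smoothed) over complex frames, with single-coil data or
#' coil-combined operators. Serves as an independent iterative oracle for
#' the deep artifact-suppression path; run it on the same 24/18 blocks and
#' keep central frames for streaming use.
#'
#' @param ksp List (per frame) of complex sample vectors.
#' @param sampling [make_frame_sampling()] list for the same frames.
#' @param shape `c(H, W)` image grid.
#' @param voxel_mm Pixel size (mm).
#' @param cfg [cs_config()].
#' @return List: `x` (complex `H x W x T`), `objective` (per-iteration,
#'   non-increasing), `converged`.
#' @export
cs_reconstruct <- function(ksp, sampling, shape, voxel_mm,
                           cfg = cs_config()) {
  t_n <- length(ksp)
  stopifnot(t_n >= 2, length(sampling) >= t_n)
  Af <- function(x, f) nufft_sample(x, sampling[[f]]$traj$k, voxel_mm)
  Ah <- function(s, f) nufft_grid(s, NULL, sampling[[f]]$traj$k, voxel_mm, shape)
  # normalize data scale so lambda is meaningful on unit-scale images
  x0 <- array(0 + 0i, dim = c(shape, t_n))
  for (f in seq_len(t_n))
    x0[, , f] <- nufft_grid(ksp[[f]], sampling[[f]]$w,
                            sampling[[f]]$traj$k, voxel_mm, shape)
  sc <- stats::quantile(abs(x0), 0.99, names = FALSE)
  if (sc <= 0) sc <- 1
  ysc <- lapply(ksp, function(s) s / sc)
  # Lipschitz estimate of A^H A by power iteration on one frame
  L <- if (is.null(cfg$step)) {
    v <- matrix(complex(real = stats::rnorm(prod(shape))), shape[1], shape[2])
    for (i in 1:8) { v <- Ah(Af(v, 1), 1); nv <- sqrt(sum(abs(v)^2)); v <- v / nv }
    2 * nv
  } else 1 / cfg$step
  eps <- cfg$tv_eps; lam <- cfg$lambda_t
  obj <- function(x) {
    fid <- 0
    for (f in seq_len(t_n)) fid <- fid + sum(abs(Af(x[, , f], f) - ysc[[f]])^2)
    dt <- x[, , -1, drop = FALSE] - x[, , -t_n, drop = FALSE]
    fid + lam * sum(sqrt(abs(dt)^2 + eps^2))
  }
  grad <- function(x) {
    g <- array(0 + 0i, dim = dim(x))
    for (f in seq_len(t_n)) g[, , f] <- 2 * Ah(Af(x[, , f], f) - ysc[[f]], f)
    dt <- x[, , -1, drop = FALSE] - x[, , -t_n, drop = FALSE]
    wdt <- dt / sqrt(abs(dt)^2 + eps^2) * lam
    g[, , -t_n] <- g[, , -t_n] - wdt
    g[, , -1] <- g[, , -1] + wdt
    g
  }
  x <- x0 / sc
  z <- x; tk <- 1
  step <- 1 / L
  objs <- numeric(cfg$n_iters + 1L)
  objs[1] <- obj(x)
  for (it in seq_len(cfg$n_iters)) {
    g <- grad(z)
    x_new <- z - step * g
    o_new <- obj(x_new)
    if (o_new > objs[it]) {           # restart momentum, backtrack from x
      z <- x; tk <- 1
      g <- grad(z)
      repeat {
        x_new <- z - step * g
        o_new <- obj(x_new)
        if (o_new <= objs[it] || step < 1e-12 / L) break
        step <- step / 2
      }
      if (o_new > objs[it]) { x_new <- x; o_new <- objs[it] }
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- x_new + ((tk - 1) / t_new) * (x_new - x)
    x <- x_new; tk <- t_new
    objs[it + 1L] <- o_new
  }
  converged <- objs[cfg$n_iters + 1L] <= objs[1]
  if (!converged) warning("CS objective did not decrease; see trace")
  list(x = x * sc, objective = objs, converged = converged)
}
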