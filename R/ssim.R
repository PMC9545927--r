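# Structural-similarity computation with analytic gradient, used both as
# the training loss of the artifact-suppression network and as an imaging
# metric. Settings: 11x11 Gaussian window (sigma 1.5), K1 = 0.01,
# K2 = 0.03, data range 1, statistics over the valid interior (no padding
# influence), mean over the SSIM map.

ssim_window <- function() gauss_kernel_1d(1.5, radius = 5)

#' Mean SSIM of two 2D images
#'
#' @param x,y Numeric matrices on a common data range (default 1).
#' @param data_range Dynamic range of the inputs.
#' @param grad If TRUE, also return the gradient of mean SSIM w.r.t. `x`.
#' @return Mean SSIM, or `list(ssim, grad)` when `grad = TRUE`.
#' @export
ssim2d <- function(x, y, data_range = 1, grad = FALSE) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch")
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  k <- ssim_window(); r <- 5L
  H <- nrow(x); W <- ncol(x)
  if (H < 11L || W < 11L) stop("images smaller than the SSIM window")
  bl <- function(m) cpp_gauss_blur2(m, k)
  iy <- (r + 1L):(H - r); ix <- (r + 1L):(W - r)
  mu_x <- bl(x)[iy, ix]; mu_y <- bl(y)[iy, ix]
  sxx <- bl(x * x)[iy, ix] - mu_x^2
  syy <- bl(y * y)[iy, ix] - mu_y^2
  sxy <- bl(x * y)[iy, ix] - mu_x * mu_y
  A1 <- 2 * mu_x * mu_y + C1; A2 <- 2 * sxy + C2
  B1 <- mu_x^2 + mu_y^2 + C1; B2 <- sxx + syy + C2
  S <- (A1 * A2) / (B1 * B2)
  ms <- mean(S)
  if (!grad) return(ms)
  n <- length(S)
  P <- A1 / B1; Q <- A2 / B2
  g1 <- Q * (2 * mu_y * B1 - 2 * mu_x * A1) / B1^2 / n
  g2 <- P * (-A2 / B2^2) / n
  g3 <- P * (2 / B2) / n
  dmu <- g1 - 2 * mu_x * g2 - mu_y * g3
  emb <- function(m) { z <- matrix(0, H, W); z[iy, ix] <- m; z }
  gx <- bl(emb(dmu)) + 2 * x * bl(emb(g2)) + y * bl(emb(g3))
  list(ssim = ms, grad = gx)
}

#' Complex-SSIM training loss for an image block
#'
#' `L = 1 - (SSIM((re(y)+1)/2, (re(yhat)+1)/2) +
#'           SSIM((im(y)+1)/2, (im(yhat)+1)/2)) / 2`,
#' with SSIM computed per 2D frame and averaged. Inputs are expected
#' normalized so channels lie in `[-1, 1]`; `L` is in `[0, 2]` and is 0
#' only when both channel SSIMs equal 1.
#'
#' @param y Truth complex array `H x W x T` (or matrix for one frame).
#' @param y_hat Prediction, same shape.
#' @param grad If TRUE also return `dL/dy_hat` as a complex array.
#' @return Scalar loss, or `list(loss, grad)`.
#' @export
ssim_pair_loss <- function(y, y_hat, grad = FALSE) {
  if (is.matrix(y)) { dim(y) <- c(dim(y), 1L); dim(y_hat) <- c(dim(y_hat), 1L) }
  if (!all(dim(y) == dim(y_hat))) stop("shape mismatch")
  t_n <- dim(y)[3]
  acc <- 0
  g <- if (grad) array(0 + 0i, dim(y)) else NULL
  for (ch in c("re", "im")) {
    pick <- if (ch == "re") Re else Im
    yt <- (pick(y) + 1) / 2
    yp <- (pick(y_hat) + 1) / 2
    r <- ssim_frames(yp, yt, grad = grad)
    if (grad) {
      # d(loss)/d(channel) = -1/(2 t_n) * dS/dyp * d(yp)/d(channel) [= 1/2]
      gch <- -r$grad / (4 * t_n)
      g <- g + if (ch == "re") gch else 1i * gch
      acc <- acc + r$ssim_sum
    } else acc <- acc + r$ssim_sum
  }
  loss <- 1 - acc / (2 * t_n)
  if (grad) list(loss = loss, grad = g) else loss
}

# per-frame SSIM over an H x W x F stack (prediction first); returns the
# sum over frames of each frame's mean SSIM, and optionally the gradient
# w.r.t. the prediction
ssim_frames <- function(x, y, grad = FALSE) {
  d <- dim(x)
  C1 <- 1e-4; C2 <- 9e-4
  k <- ssim_window(); r <- 5L
  H <- d[1]; W <- d[2]
  bl <- function(a) cpp_gauss_blur3(a, d, k)
  iy <- (r + 1L):(H - r); ix <- (r + 1L):(W - r)
  sub <- function(a) a[iy, ix, , drop = FALSE]
  mu_x <- sub(bl(x)); mu_y <- sub(bl(y))
  sxx <- sub(bl(x * x)) - mu_x^2
  syy <- sub(bl(y * y)) - mu_y^2
  sxy <- sub(bl(x * y)) - mu_x * mu_y
  A1 <- 2 * mu_x * mu_y + C1; A2 <- 2 * sxy + C2
  B1 <- mu_x^2 + mu_y^2 + C1; B2 <- sxx + syy + C2
  S <- (A1 * A2) / (B1 * B2)
  n <- length(S) / d[3]          # interior pixels per frame
  ssim_sum <- sum(S) / n
  if (!grad) return(list(ssim_sum = ssim_sum))
  P <- A1 / B1; Q <- A2 / B2
  g1 <- Q * (2 * mu_y * B1 - 2 * mu_x * A1) / B1^2 / n
  g2 <- P * (-A2 / B2^2) / n
  g3 <- P * (2 / B2) / n
  dmu <- g1 - 2 * mu_x * g2 - mu_y * g3
  emb <- function(a) { z <- array(0, d); z[iy, ix, ] <- a; z }
  gx <- bl(emb(dmu)) + 2 * x * bl(emb(g2)) + y * bl(emb(g3))
  list(ssim_sum = ssim_sum, grad = gx)
}
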