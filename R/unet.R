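# Compact 2D+time U-Net engine. Activations are N x C matrices with voxel
# index n = t + T*(h + H*w); 3x3x3 convolution is im2col (C++) followed by
# BLAS matrix multiplication, so the whole network trains on one CPU at
# desk scale. No external deep-learning framework is required.

#' U-Net hyperparameter specification
#'
#' @param n_scales Resolution levels (downsampling x2 per level).
#' @param init_filters Channels at the finest scale (doubled per level).
#' @param blocks_per_scale 3x3x3 convolutions per level.
#' @param lr Adam learning rate.
#' @return Object of class `unet_spec`.
#' @export
unet_spec <- function(n_scales = 3, init_filters = 16, blocks_per_scale = 2,
                      lr = 1e-3) {
  stopifnot(n_scales >= 1, init_filters >= 4, blocks_per_scale >= 1, lr > 0)
  structure(list(n_scales = n_scales, init_filters = init_filters,
                 blocks_per_scale = blocks_per_scale, lr = lr),
            class = "unet_spec")
}

he_init <- function(n_out, n_in_eff, n_in_cols) {
  matrix(stats::rnorm(n_out * n_in_cols, 0, sqrt(2 / n_in_eff)),
         n_in_cols, n_out)
}

#' Build a 2D+time U-Net
#'
#' Encoder-decoder over (t, y, x) with skip connections: each level applies
#' `blocks_per_scale` 3x3x3 convolutions (leaky ReLU, 0.1) and 2x average
#' pooling; the decoder upsamples (nearest), concatenates the skip, fuses
#' with a 1x1x1 convolution and applies the level's 3x3x3 convolutions.
#' The linear 1x1x1 output head is zero-initialized, so with
#' `residual = TRUE` (the default) the freshly built network is the
#' identity map.
#'
#' @param spec [unet_spec()].
#' @param in_channels,out_channels Input/output channels (real, imaginary).
#' @param residual Add the first `out_channels` input channels to the output.
#' @param seed Weight-initialization seed.
#' @return Object of class `unet_model`; `n_params` reports the size.
#' @export
build_unet <- function(spec, in_channels = 2, out_channels = 2,
                       residual = TRUE, seed = 1) {
  stopifnot(inherits(spec, "unet_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  S <- spec$n_scales; B <- spec$blocks_per_scale
  f <- spec$init_filters * 2^(seq_len(S) - 1L)
  enc <- vector("list", S); dec <- vector("list", max(S - 1L, 0L))
  for (s in seq_len(S)) {
    cin <- if (s == 1L) in_channels else f[s - 1L]
    layers <- list()
    for (b in seq_len(B)) {
      ci <- if (b == 1L) cin else f[s]
      layers[[b]] <- list(W = he_init(f[s], ci * 27, ci * 27),
                          b = rep(0, f[s]), k = 3L, cin = ci, cout = f[s])
    }
    enc[[s]] <- layers
  }
  for (s in rev(seq_len(S - 1L))) {
    cin <- f[s] + f[s + 1L]
    layers <- list(list(W = he_init(f[s], cin, cin), b = rep(0, f[s]),
                        k = 1L, cin = cin, cout = f[s]))
    for (b in seq_len(B))
      layers[[b + 1L]] <- list(W = he_init(f[s], f[s] * 27, f[s] * 27),
                               b = rep(0, f[s]), k = 3L, cin = f[s], cout = f[s])
    dec[[s]] <- layers
  }
  head <- list(W = matrix(0, f[1], out_channels), b = rep(0, out_channels),
               k = 1L, cin = f[1], cout = out_channels)
  model <- structure(list(spec = spec, in_channels = in_channels,
                          out_channels = out_channels, residual = residual,
                          enc = enc, dec = dec, head = head),
                     class = "unet_model")
  model$n_params <- sum(vapply(unet_flatten(model),
                               function(p) length(p$W) + length(p$b), 0))
  model
}

unet_flatten <- function(model) {
  out <- list()
  for (s in seq_along(model$enc)) for (l in model$enc[[s]])
    out[[length(out) + 1L]] <- l
  for (s in seq_along(model$dec)) if (!is.null(model$dec[[s]]))
    for (l in model$dec[[s]]) out[[length(out) + 1L]] <- l
  out[[length(out) + 1L]] <- model$head
  out
}

lrelu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)
lrelu_g <- function(x) ifelse(x > 0, 1, 0.1)

conv_fwd <- function(X, dims, layer) {
  K <- if (layer$k == 3L) cpp_im2col3(X, dims, 3L) else X
  Y <- K %*% layer$W
  for (c in seq_along(layer$b))
    if (layer$b[c] != 0) Y[, c] <- Y[, c] + layer$b[c]
  list(Y = Y, K = K)
}

conv_bwd <- function(dY, cache, dims, layer) {
  dW <- crossprod(cache$K, dY)
  db <- colSums(dY)
  dK <- tcrossprod(dY, layer$W)
  dX <- if (layer$k == 3L) cpp_col2im3(dK, dims, 3L, layer$cin) else dK
  list(dX = dX, dW = dW, db = db)
}

#' Apply a U-Net to an input block
#'
#' @param model [build_unet()] output.
#' @param X Input `N x in_channels` matrix (see [block_to_mat()]).
#' @param dims `c(T, H, W)` of the block; `H`, `W` and (for multi-scale
#'   models) `T` must be divisible by `2^(n_scales - 1)`.
#' @param cache Keep intermediate activations for backprop.
#' @return `N x out_channels` matrix, or `list(Y, cache)` when caching.
#' @export
unet_forward <- function(model, X, dims, cache = FALSE) {
  S <- model$spec$n_scales
  div <- 2^(S - 1L)
  if (any(dims[2:3] %% div != 0) || (S > 1L && dims[1] %% div != 0))
    stop("block dims not divisible by the U-Net scale factor")
  cc <- list(enc = vector("list", S), dec = vector("list", S), dims = list())
  skips <- vector("list", S)
  cur <- X; cd <- dims
  for (s in seq_len(S)) {
    lcache <- list()
    for (li in seq_along(model$enc[[s]])) {
      cv <- conv_fwd(cur, cd, model$enc[[s]][[li]])
      lcache[[li]] <- list(K = cv$K, pre = cv$Y, Xin = cur)
      cur <- lrelu(cv$Y)
    }
    cc$enc[[s]] <- lcache
    cc$dims[[s]] <- cd
    if (s < S) { skips[[s]] <- cur; cur <- cpp_avgpool3(cur, cd); cd <- cd %/% 2L }
  }
  for (s in rev(seq_len(S - 1L))) {
    cur <- cpp_upsample3(cur, cd)
    cd <- cd * 2L
    cur <- cbind(skips[[s]], cur)
    lcache <- list()
    for (li in seq_along(model$dec[[s]])) {
      cv <- conv_fwd(cur, cd, model$dec[[s]][[li]])
      lcache[[li]] <- list(K = cv$K, pre = cv$Y, Xin = cur)
      cur <- lrelu(cv$Y)
    }
    cc$dec[[s]] <- lcache
  }
  hv <- conv_fwd(cur, cd, model$head)
  Y <- hv$Y
  if (model$residual) Y <- Y + X[, seq_len(model$out_channels), drop = FALSE]
  if (!cache) return(Y)
  cc$head <- list(K = hv$K)
  list(Y = Y, cache = cc)
}

# backward pass: returns gradients in the same nested structure
unet_backward <- function(model, dY, cache) {
  S <- model$spec$n_scales
  g <- list(enc = vector("list", S), dec = vector("list", S), head = NULL)
  hb <- list(dW = crossprod(cache$head$K, dY), db = colSums(dY))
  cur <- tcrossprod(dY, model$head$W)
  g$head <- hb
  skip_grads <- vector("list", S)
  for (s in seq_len(S - 1L)) {
    cd <- cache$dims[[s]]
    lcache <- cache$dec[[s]]
    lg <- vector("list", length(lcache))
    for (li in rev(seq_along(lcache))) {
      layer <- model$dec[[s]][[li]]
      dpre <- cur * lrelu_g(lcache[[li]]$pre)
      bw <- conv_bwd(dpre, lcache[[li]], cd, layer)
      lg[[li]] <- list(dW = bw$dW, db = bw$db)
      cur <- bw$dX
    }
    g$dec[[s]] <- lg
    nsk <- ncol(cache$enc[[s]][[length(cache$enc[[s]])]]$pre)
    skip_grads[[s]] <- cur[, seq_len(nsk), drop = FALSE]
    # gradient w.r.t. the upsample input = output of the next-deeper stage
    cur <- cpp_upsample3_bwd(cur[, -seq_len(nsk), drop = FALSE], cd %/% 2L)
  }
  for (s in rev(seq_len(S))) {
    cd <- cache$dims[[s]]
    if (s < S) cur <- cpp_avgpool3_bwd(cur, cd) + skip_grads[[s]]
    lcache <- cache$enc[[s]]
    lg <- vector("list", length(lcache))
    for (li in rev(seq_along(lcache))) {
      layer <- model$enc[[s]][[li]]
      dpre <- cur * lrelu_g(lcache[[li]]$pre)
      bw <- conv_bwd(dpre, lcache[[li]], cd, layer)
      lg[[li]] <- list(dW = bw$dW, db = bw$db)
      cur <- bw$dX
    }
    g$enc[[s]] <- lg
  }
  g
}

#' Convert a complex image block to network input layout
#'
#' @param block Complex array `H x W x T`.
#' @return List `X` (`(T*H*W) x 2` real/imag matrix) and `dims` `c(T, H, W)`.
#' @export
block_to_mat <- function(block) {
  d <- dim(block)
  a <- aperm(block, c(3, 1, 2))
  list(X = cbind(Re(a), Im(a)) |> (\(m) { dim(m) <- c(prod(d), 2L); m })(),
       dims = c(d[3], d[1], d[2]))
}

#' Convert network output back to a complex block
#'
#' @param Y `N x 2` matrix.
#' @param dims `c(T, H, W)`.
#' @return Complex array `H x W x T`.
#' @export
mat_to_block <- function(Y, dims) {
  a <- array(complex(real = Y[, 1], imaginary = Y[, 2]), dim = dims)
  aperm(a, c(2, 3, 1))
}
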