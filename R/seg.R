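# Aortic segmentation: CLAHE preprocessing, segmentation losses, and the
# segmentation U-Net trained on complex phase-contrast blocks.

#' Contrast-limited adaptive histogram equalization of magnitude frames
#'
#' Applied per frame with the given clip limit and tile grid; input and
#' output are in [0, 1].
#'
#' @param magnitude Matrix or `H x W x T` array of magnitudes in [0, 1].
#' @param clip_limit Normalized clip limit (fraction of a tile's
#'   histogram; default 0.02).
#' @param tile_grid `c(nx, ny)` tiles (default 8 x 8).
#' @return Equalized array of the same shape, clamped to [0, 1].
#' @export
clahe_equalize <- function(magnitude, clip_limit = 0.02, tile_grid = c(8, 8)) {
  if (any(!is.finite(magnitude))) stop("non-finite input to CLAHE")
  one <- function(m) {
    if (max(m) - min(m) < 1e-8) return(m)  # constant frame: nothing to equalize
    e <- EBImage::clahe(m, nx = tile_grid[1], ny = tile_grid[2],
                        limit = clip_limit * 100, keep.range = FALSE)
    pmin(pmax(as.matrix(e), 0), 1)
  }
  if (is.matrix(magnitude)) return(one(magnitude))
  out <- magnitude
  for (f in seq_len(dim(magnitude)[3])) out[, , f] <- one(magnitude[, , f])
  out
}

#' Segmentation losses
#'
#' `"bce"` is epsilon-clipped binary cross entropy; `"dice"` is the soft
#' Dice loss `1 - (2 sum(pg) + eps) / (sum(p) + sum(g) + eps)`;
#' `"bce_dice"` is their sum (the training default).
#'
#' @param name One of `"bce"`, `"dice"`, `"bce_dice"`.
#' @param truth Logical/0-1 mask (any shape).
#' @param prob Predicted probabilities, same shape.
#' @return Scalar loss.
#' @export
seg_loss <- function(name, truth, prob) {
  name <- match.arg(name, c("bce", "dice", "bce_dice"))
  if (!all(dim(truth) == dim(prob)) || length(truth) != length(prob))
    stop("shape mismatch")
  g <- as.numeric(truth); p <- as.numeric(prob)
  eps <- 1e-7
  bce <- function() {
    pc <- pmin(pmax(p, eps), 1 - eps)
    -mean(g * log(pc) + (1 - g) * log(1 - pc))
  }
  dice <- function() 1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
  switch(name, bce = bce(), dice = dice(), bce_dice = bce() + dice())
}

# loss and gradient w.r.t. logits for training
seg_loss_grad <- function(name, truth, logits) {
  g <- as.numeric(truth)
  p <- 1 / (1 + exp(-as.numeric(logits)))
  n <- length(g); eps <- 1e-7
  loss <- 0; dp <- numeric(n)
  if (name %in% c("bce", "bce_dice")) {
    pc <- pmin(pmax(p, eps), 1 - eps)
    loss <- loss - mean(g * log(pc) + (1 - g) * log(1 - pc))
    dp <- dp + (pc - g) / (pc * (1 - pc)) / n
  }
  if (name %in% c("dice", "bce_dice")) {
    den <- sum(p) + sum(g) + eps
    num <- 2 * sum(p * g) + eps
    loss <- loss + 1 - num / den
    dp <- dp + (-2 * g * den + num) / den^2
  }
  dlogit <- dp * p * (1 - p)
  list(loss = loss, dlogit = dlogit, prob = p)
}

#' Train the aortic segmentation network
#'
#' The input of each case is a complex phase-contrast block whose
#' magnitude has been CLAHE-equalized (see [seg_input()]); the target is
#' the vessel mask block. Optimizes the chosen segmentation loss with
#' Adam, one block per step.
#'
#' @param cases List of `list(input = complex H x W x T, mask = logical)`.
#' @param spec [unet_spec()].
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @param loss `"bce"`, `"dice"` or `"bce_dice"` (default).
#' @param val_cases Optional held-out cases; per-epoch validation Dice.
#' @param verbose Print progress.
#' @return List of class `segmenter`: `model`, `history`, `loss`.
#' @export
train_segmenter <- function(cases, spec, epochs = 8, seed = 1,
                            loss = "bce_dice", val_cases = NULL,
                            verbose = FALSE) {
  stopifnot(length(cases) >= 1)
  loss <- match.arg(loss, c("bce", "dice", "bce_dice"))
  model <- build_unet(spec, 2, 1, residual = FALSE, seed = seed)
  st <- adam_state_new()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_dice = numeric())
  for (ep in seq_len(epochs)) {
    tl <- 0
    for (i in sample(seq_along(cases))) {
      cs <- cases[[i]]
      bm <- block_to_mat(cs$input)
      fw <- unet_forward(model, bm$X, bm$dims, cache = TRUE)
      tgt <- aperm(array(cs$mask, dim(cs$input)), c(3, 1, 2))
      lg <- seg_loss_grad(loss, as.numeric(tgt), fw$Y[, 1])
      if (!is.finite(lg$loss))
        stop("training aborted: non-finite loss at epoch ", ep, ", case ", i)
      tl <- tl + lg$loss
      grads <- unet_backward(model, matrix(lg$dlogit, ncol = 1), fw$cache)
      step <- step + 1L
      model <- unet_apply_grads(model, grads, st, spec$lr, step)
    }
    vd <- if (!is.null(val_cases))
      mean(vapply(val_cases, function(cs) {
        sg <- segment(model, cs$input)
        dice_score(cs$mask, sg$mask)
      }, 0))
    else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / length(cases),
                                   val_dice = vd))
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val dice %.4f", ep,
                      tl / length(cases), vd))
  }
  structure(list(model = model, history = hist, loss = loss),
            class = "segmenter")
}

#' Build the segmentation-network input from a phase-contrast block
#'
#' Magnitudes are normalized to [0, 1] (by the block's 99th percentile),
#' CLAHE-equalized, and recombined with the subtracted phase into a
#' complex block.
#'
#' @param pc_block Complex phase-contrast block `H x W x T`.
#' @param clip_limit,tile_grid CLAHE parameters.
#' @return Complex block of the same shape.
#' @export
seg_input <- function(pc_block, clip_limit = 0.02, tile_grid = c(8, 8)) {
  mag <- abs(pc_block)
  sc <- stats::quantile(mag, 0.99, names = FALSE)
  if (sc <= 0) sc <- 1
  magn <- pmin(mag / sc, 1)
  eq <- clahe_equalize(magn, clip_limit, tile_grid)
  eq * exp(1i * Arg(pc_block))
}

#' Segment a phase-contrast block
#'
#' @param model `segmenter` (or bare `unet_model`).
#' @param pc_block Complex block, already CLAHE-prepared ([seg_input()]).
#' @param threshold Probability threshold for the hard mask.
#' @param largest_component Keep only the largest connected component per
#'   frame (off by default).
#' @return List: `prob` (array in [0,1]), `mask` (logical array).
#' @export
segment <- function(model, pc_block, threshold = 0.5,
                    largest_component = FALSE) {
  if (inherits(model, "segmenter")) model <- model$model
  bm <- block_to_mat(pc_block)
  Y <- unet_forward(model, bm$X, bm$dims)
  prob_t <- array(1 / (1 + exp(-Y[, 1])), bm$dims)
  prob <- aperm(prob_t, c(2, 3, 1))
  mask <- prob >= threshold
  if (largest_component) {
    for (f in seq_len(dim(mask)[3])) {
      lab <- EBImage::bwlabel(mask[, , f] * 1)
      if (max(lab) > 1) {
        sizes <- tabulate(lab[lab > 0])
        mask[, , f] <- lab == which.max(sizes)
      }
    }
  }
  list(prob = prob, mask = mask)
}

dice_score <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
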