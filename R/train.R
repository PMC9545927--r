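# Training engine: Adam updates over the nested U-Net parameter structure,
# the artifact-suppression trainer (complex-SSIM loss) and a reduced
# successive-halving hyperparameter search.

adam_state_new <- function() new.env(parent = emptyenv())

adam_update <- function(layer, grad, st, key, lr, step,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  s <- if (!is.null(st[[key]])) st[[key]] else
    list(mW = layer$W * 0, vW = layer$W * 0, mb = layer$b * 0, vb = layer$b * 0)
  s$mW <- b1 * s$mW + (1 - b1) * grad$dW
  s$vW <- b2 * s$vW + (1 - b2) * grad$dW^2
  s$mb <- b1 * s$mb + (1 - b1) * grad$db
  s$vb <- b2 * s$vb + (1 - b2) * grad$db^2
  corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
  layer$W <- layer$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
  layer$b <- layer$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
  st[[key]] <- s
  layer
}

unet_apply_grads <- function(model, grads, st, lr, step) {
  for (s in seq_along(model$enc))
    for (li in seq_along(model$enc[[s]]))
      model$enc[[s]][[li]] <- adam_update(model$enc[[s]][[li]],
                                          grads$enc[[s]][[li]], st,
                                          paste0("e", s, "_", li), lr, step)
  for (s in seq_along(model$dec))
    if (!is.null(model$dec[[s]]))
      for (li in seq_along(model$dec[[s]]))
        model$dec[[s]][[li]] <- adam_update(model$dec[[s]][[li]],
                                            grads$dec[[s]][[li]], st,
                                            paste0("d", s, "_", li), lr, step)
  model$head <- adam_update(model$head, grads$head, st, "head", lr, step)
  model
}

grad_to_mat <- function(g) {
  a <- aperm(g, c(3, 1, 2))
  cbind(as.vector(Re(a)), as.vector(Im(a)))
}

#' Train the deep artifact-suppression network
#'
#' Minimizes the complex-SSIM loss [ssim_pair_loss()] over corrupted/truth
#' blocks with Adam (batch = one block). Training aborts with diagnostics
#' if the loss becomes non-finite.
#'
#' @param pairs List of [training_pair()]s.
#' @param spec [unet_spec()].
#' @param epochs Training epochs.
#' @param seed Seed for init and block shuffling.
#' @param val_pairs Optional held-out pairs for a per-epoch validation loss.
#' @param residual Use the global residual connection (default TRUE).
#' @param verbose Print per-epoch losses.
#' @param init_model Optional `suppressor` or `unet_model` to continue
#'   training from (warm start).
#' @param augment Apply [augment_pair()] to each block draw (fresh random
#'   transform per epoch).
#' @param p_translate Translation-augmentation probability when `augment`.
#' @return List of class `suppressor`: `model`, `history` (data frame with
#'   epoch, train_loss, val_loss).
#' @export
train_suppressor <- function(pairs, spec, epochs = 8, seed = 1,
                             val_pairs = NULL, residual = TRUE,
                             verbose = FALSE, init_model = NULL,
                             augment = FALSE, p_translate = 0.5) {
  stopifnot(length(pairs) >= 1)
  model <- if (is.null(init_model)) {
    build_unet(spec, 2, 2, residual = residual, seed = seed)
  } else if (inherits(init_model, "suppressor")) init_model$model
  else init_model
  st <- adam_state_new()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (ep in seq_len(epochs)) {
    tl <- 0
    for (i in sample(seq_along(pairs))) {
      p <- pairs[[i]]
      if (augment) p <- augment_pair(p, p_translate = p_translate)
      bm <- block_to_mat(p$corrupted)
      fw <- unet_forward(model, bm$X, bm$dims, cache = TRUE)
      pred <- mat_to_block(fw$Y, bm$dims)
      sl <- ssim_pair_loss(p$truth, pred, grad = TRUE)
      if (!is.finite(sl$loss))
        stop("training aborted: non-finite loss at epoch ", ep, ", block ", i)
      tl <- tl + sl$loss
      grads <- unet_backward(model, grad_to_mat(sl$grad), fw$cache)
      step <- step + 1L
      model <- unet_apply_grads(model, grads, st, spec$lr, step)
    }
    vl <- if (!is.null(val_pairs))
      mean(vapply(val_pairs, function(p)
        ssim_pair_loss(p$truth, suppress_block(model, p$corrupted)), 0))
    else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / length(pairs),
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val %.4f", ep,
                      tl / length(pairs), vl))
  }
  structure(list(model = model, history = hist), class = "suppressor")
}

suppress_block <- function(model, block) {
  bm <- block_to_mat(block)
  mat_to_block(unet_forward(model, bm$X, bm$dims), bm$dims)
}

#' Apply deep artifact suppression to a normalized block
#'
#' Each encoding of a flow-encoded/compensated pair is passed through the
#' model independently; a bare complex block is restored directly. The
#' model is stateless, so repeated application is well defined.
#'
#' @param model `suppressor` (or bare `unet_model`).
#' @param block Complex array `H x W x T`, or a list with `comp` and `enc`
#'   members (an encoding-pair block), normalized to unit scale.
#' @return Restored object of the same shape/class.
#' @export
suppress <- function(model, block) {
  if (inherits(model, "suppressor")) model <- model$model
  if (is.list(block) && !is.null(block$comp)) {
    block$comp <- suppress_block(model, block$comp)
    block$enc <- suppress_block(model, block$enc)
    return(block)
  }
  suppress_block(model, block)
}

#' Reduced successive-halving hyperparameter search
#'
#' Evaluates all candidate specifications for a small epoch allowance,
#' keeps the best third, triples the allowance, and repeats until one
#' candidate remains. Total epochs spent never exceed `budget`.
#'
#' @param space List of [unet_spec()] candidates.
#' @param budget Total epoch budget across all evaluations.
#' @param eval_fn `function(spec, epochs)` returning a validation loss.
#' @param factor Elimination factor (keep `1/factor` per round).
#' @return List: `best` spec, `trace` data frame (round, candidate, epochs,
#'   score), `epochs_used`.
#' @export
successive_halving_search <- function(space, budget, eval_fn, factor = 3) {
  stopifnot(length(space) >= 1, budget >= 1)
  surv <- seq_along(space)
  n_rounds <- max(1L, ceiling(log(length(space)) / log(factor)))
  per_round <- budget %/% n_rounds
  used <- 0L; round <- 0L
  trace <- data.frame()
  while (TRUE) {
    round <- round + 1L
    r <- max(1L, per_round %/% length(surv))
    if (used + r * length(surv) > budget)
      r <- max(0L, (budget - used) %/% length(surv))
    if (r == 0L) break
    scores <- vapply(surv, function(i) eval_fn(space[[i]], r), 0)
    used <- used + r * length(surv)
    trace <- rbind(trace, data.frame(round = round, candidate = surv,
                                     epochs = r, score = scores))
    if (length(surv) == 1L) break
    keep <- max(1L, ceiling(length(surv) / factor))
    surv <- surv[order(scores)][seq_len(keep)]
  }
  best <- if (nrow(trace)) {
    last <- trace[trace$round == max(trace$round), ]
    space[[last$candidate[which.min(last$score)]]]
  } else space[[1]]
  list(best = best, trace = trace, epochs_used = used)
}
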