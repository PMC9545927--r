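# Imaging, segmentation and agreement metrics.

#' Imaging metrics between normalized magnitude series
#'
#' MAE, PSNR (`10 log10(1/MSE)`, capped at 100 dB) and mean SSIM (same
#' window settings as the training loss), computed over magnitude images
#' in [0, 1].
#'
#' @param truth,pred Arrays `H x W x T` (or matrices) of magnitudes.
#' @return List `mae`, `psnr`, `ssim`.
#' @export
image_metrics <- function(truth, pred) {
  if (!all(dim(truth) == dim(pred))) stop("shape mismatch")
  if (is.matrix(truth)) { dim(truth) <- c(dim(truth), 1L); dim(pred) <- dim(truth) }
  mae <- mean(abs(truth - pred))
  mse <- mean((truth - pred)^2)
  psnr <- if (mse == 0) 100 else min(10 * log10(1 / mse), 100)
  ss <- mean(vapply(seq_len(dim(truth)[3]), function(f)
    ssim2d(pred[, , f], truth[, , f]), 0))
  list(mae = mae, psnr = psnr, ssim = ss)
}

#' Segmentation metrics
#'
#' Epsilon-clipped binary cross entropy of the probabilities and hard Dice
#' at threshold 0.5.
#'
#' @param truth Logical/0-1 mask.
#' @param prob Predicted probabilities, same shape.
#' @return List `bce`, `dice`.
#' @export
seg_metrics <- function(truth, prob) {
  if (!all(dim(truth) == dim(prob))) stop("shape mismatch")
  list(bce = seg_loss("bce", truth, prob),
       dice = dice_score(truth, prob >= 0.5))
}

#' Bland-Altman agreement between paired measurements
#'
#' Bias is `mean(a - b)`; 95% limits of agreement are
#' `bias +/- 1.96 sd(a - b)` (sample s.d.); the p-value is a two-sided
#' paired t-test.
#'
#' @param a,b Paired numeric vectors (n >= 2).
#' @return Object of class `agreement_report`: list with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `p_paired_t`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("unpaired lengths")
  stopifnot(length(a) >= 2)
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  p <- if (s == 0) NA_real_ else stats::t.test(a, b, paired = TRUE)$p.value
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 p_paired_t = p, n = length(a)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f [LoA %.3f, %.3f], paired-t p = %s\n",
              x$n, x$bias, x$loa_low, x$loa_high,
              ifelse(is.na(x$p_paired_t), "NA", sprintf("%.3g", x$p_paired_t))))
  invisible(x)
}
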