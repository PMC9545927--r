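# Gridding NUFFT (Kaiser-Bessel interpolation on a 2x oversampled grid).
# Conventions: unnormalized type-2/type-1 transforms, DC at the grid centre
# (even grid sizes), k in cycles/mm, pixel positions measured in mm from the
# grid centre. Forward and adjoint use the same kernel and real
# deapodization, so they form an exact adjoint pair by construction.

# Beatty et al. kernel shape parameter for a given width / oversampling
kb_beta <- function(width, osf) {
  pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
}

nufft_prep <- function(shape, k, voxel_mm, osf, width) {
  H <- shape[1]; W <- shape[2]
  if (H %% 2L || W %% 2L) stop("grid dimensions must be even")
  kmax <- 1 / (2 * voxel_mm)
  if (max(abs(k)) > kmax * (1 + 1e-9))
    stop("out-of-band k-space coordinate beyond +/- k_max")
  beta <- kb_beta(width, osf)
  nosH <- as.integer(osf * H); nosW <- as.integer(osf * W)
  ty <- (0:(H - 1L)) - H %/% 2L; tx <- (0:(W - 1L)) - W %/% 2L
  list(H = H, W = W, nosH = nosH, nosW = nosW, beta = beta,
       deapod = outer(cpp_kb_ft(ty / nosH, width, beta),
                      cpp_kb_ft(tx / nosW, width, beta)),
       ridx = (ty %% nosH) + 1L, cidx = (tx %% nosW) + 1L,
       gy = k[, 2] * voxel_mm * H * osf, gx = k[, 1] * voxel_mm * W * osf)
}

#' Nonuniform Fourier sampling of an image (type-2 NUFFT)
#'
#' Evaluates `s_j = sum_x img(x) exp(-2 pi i k_j . r_x)` with `r_x` in mm
#' from the image centre, via deapodized zero-padded FFT and Kaiser-Bessel
#' interpolation. Unnormalized: a constant image `c` gives `c * H * W` at
#' the k-space origin.
#'
#' @param image Complex (or numeric) H x W matrix, rows = y.
#' @param k n x 2 matrix of (kx, ky) in cycles/mm; must lie within
#'   `+/- 1/(2 voxel_mm)`.
#' @param voxel_mm Pixel size in mm.
#' @param osf Oversampling factor (default 2).
#' @param width Kernel width in oversampled grid units (default 8,
#'   about 1e-9 relative accuracy).
#' @return Complex vector of k-space samples.
#' @export
nufft_sample <- function(image, k, voxel_mm, osf = 2, width = 8) {
  p <- nufft_prep(dim(image), k, voxel_mm, osf, width)
  A <- matrix(0 + 0i, p$nosH, p$nosW)
  A[p$ridx, p$cidx] <- image / p$deapod
  K <- stats::fft(A)
  as.vector(cpp_kb_interp(K, p$gy, p$gx, width, p$beta))
}

#' Density-weighted adjoint gridding (type-1 NUFFT)
#'
#' Adjoint of [nufft_sample()]: spreads (optionally density-compensated)
#' samples onto the oversampled k-grid, inverse-FFTs and deapodizes.
#'
#' @param samples Complex vector of k-space samples.
#' @param weights Density-compensation weights (NULL for unweighted adjoint).
#' @param k n x 2 sample coordinates in cycles/mm.
#' @param voxel_mm Pixel size in mm.
#' @param shape `c(H, W)` of the output grid.
#' @param osf,width As in [nufft_sample()].
#' @return Complex H x W matrix.
#' @export
nufft_grid <- function(samples, weights, k, voxel_mm, shape, osf = 2, width = 8) {
  if (!is.null(weights)) {
    if (length(weights) != length(samples))
      stop("weights length does not match sample count")
    samples <- samples * weights
  }
  if (length(samples) != nrow(k)) stop("sample/trajectory length mismatch")
  p <- nufft_prep(shape, k, voxel_mm, osf, width)
  K <- cpp_kb_spread(as.complex(samples), p$gy, p$gx, p$nosH, p$nosW,
                     width, p$beta)
  B <- stats::fft(K, inverse = TRUE)
  B[p$ridx, p$cidx] / p$deapod
}

#' Sample an image along a frame trajectory
#'
#' Module-level wrapper around [nufft_sample()] taking a [frame_trajectory()].
#'
#' @param image Complex H x W frame.
#' @param traj [frame_trajectory()].
#' @param voxel_mm Pixel size in mm (defaults to the trajectory's params).
#' @return Complex vector of k-space samples.
#' @export
sample_image <- function(image, traj, voxel_mm = traj$params$voxel_mm) {
  nufft_sample(image, traj$k, voxel_mm)
}

#' Grid k-space samples of one frame onto the image grid
#'
#' @param samples Complex samples from [sample_image()] or acquisition.
#' @param weights Density-compensation weights ([density_compensation()]).
#' @param traj [frame_trajectory()].
#' @param shape `c(H, W)` output grid.
#' @param voxel_mm Pixel size in mm.
#' @return Complex H x W frame.
#' @export
grid_samples <- function(samples, weights, traj, shape,
                         voxel_mm = traj$params$voxel_mm) {
  nufft_grid(samples, weights, traj$k, voxel_mm, shape)
}
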