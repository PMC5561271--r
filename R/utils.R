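# Internal numerical helpers shared by the generator and the cluster module.

# Stationary AR(1) noise, n series (rows) x t timepoints, marginal sd = sd.
# coef = 0 reduces to white noise without the recursion.
ar1_noise <- function(n, t, coef = 0, sd = 1) {
  if (coef == 0) return(matrix(stats::rnorm(n * t, sd = sd), n, t))
  stopifnot(abs(coef) < 1)
  x <- matrix(0, n, t)
  x[, 1] <- stats::rnorm(n, sd = sd)
  innov_sd <- sd * sqrt(1 - coef^2)
  for (k in 2:t) x[, k] <- coef * x[, k - 1] + stats::rnorm(n, sd = innov_sd)
  x
}

# 1D Gaussian convolution matrix (n x n) for kernel FWHM in voxel units,
# truncated at 3 sd and renormalized row-wise at the edges.
gaussian_kernel_matrix <- function(n, fwhm_vox) {
  if (fwhm_vox <= 0 || n == 1L) return(diag(n))
  sigma <- fwhm_vox / sqrt(8 * log(2))
  half <- max(1L, ceiling(3 * sigma))
  offs <- -half:half
  w <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

#' Separable 3D Gaussian smoothing
#'
#' Smooths a 3D array with a separable Gaussian kernel of the given FWHM,
#' truncated at 3 sigma and renormalized at the volume edges. Used by the
#' synthetic generator and by the Monte-Carlo null fields; exported so
#' smoothness-recovery experiments can plant a known FWHM.
#'
#' @param arr numeric 3D array.
#' @param fwhm_mm kernel FWHM in mm (scalar or per-axis triple); 0 = no-op.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return The smoothed array.
#' @export
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size_mm) {
  d <- dim(arr)
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  if (all(fwhm_mm <= 0)) return(arr)
  for (axis in 1:3) {
    K <- gaussian_kernel_matrix(d[axis], fwhm_mm[axis] / voxel_size_mm[axis])
    if (axis == 1L) {
      arr <- array(K %*% matrix(arr, d[1], d[2] * d[3]), d)
    } else if (axis == 2L) {
      m <- matrix(aperm(arr, c(2, 1, 3)), d[2], d[1] * d[3])
      arr <- aperm(array(K %*% m, d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      m <- matrix(aperm(arr, c(3, 1, 2)), d[3], d[1] * d[2])
      arr <- aperm(array(K %*% m, d[c(3, 1, 2)]), c(2, 3, 1))
    }
  }
  arr
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. Deterministic given `seed`.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
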