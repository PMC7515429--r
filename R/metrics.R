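# Quantitative evaluation on the 0-255 intensity scale.

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in decibels.  Identical images have zero MSE;
#' the PSNR is then reported as `Inf` (flagged, not an error).
#'
#' @param ref,test real matrices of equal shape.
#' @param peak peak intensity (255 for 8-bit images).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(ref, test, peak = 255) {
  if (!identical(dim(ref), dim(test))) stop_dim("image shapes differ")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# Gaussian kernel as used by standard SSIM (sigma 1.5, radius 5 -> 11 taps)
ssim_kernel <- function(sigma = 1.5, radius = 5L) {
  x <- (-radius):radius
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

# separable convolution with reflect padding (edge pixel duplicated)
conv_reflect <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  pad1 <- function(m) {
    n <- nrow(m)
    rbind(m[r:1, , drop = FALSE], m, m[n:(n - r + 1), , drop = FALSE])
  }
  along_rows <- function(m) {
    mp <- pad1(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(along_rows(t(along_rows(x))))
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5), constants
#' `K1 = 0.01`, `K2 = 0.03`, dynamic range `L = 255`, population
#' (weighted) covariances, reflect boundary handling, and the mean taken
#' over the interior (a 5-pixel border strip is ignored to avoid edge
#' effects).
#'
#' @param ref,test real matrices of equal shape.
#' @param K1,K2 stability constants.
#' @param L dynamic range of the intensities.
#' @param sigma Gaussian window standard deviation.
#' @return scalar in [-1, 1]; 1 for identical images.
#' @export
ssim <- function(ref, test, K1 = 0.01, K2 = 0.03, L = 255, sigma = 1.5) {
  if (!identical(dim(ref), dim(test))) stop_dim("image shapes differ")
  k <- ssim_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  ux <- conv_reflect(ref, k);  uy <- conv_reflect(test, k)
  uxx <- conv_reflect(ref * ref, k)
  uyy <- conv_reflect(test * test, k)
  uxy <- conv_reflect(ref * test, k)
  vx <- uxx - ux^2; vy <- uyy - uy^2; vxy <- uxy - ux * uy
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
       ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  interior <- S[(r + 1):(nrow(S) - r), (r + 1):(ncol(S) - r)]
  mean(interior)
}
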