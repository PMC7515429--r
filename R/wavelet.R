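# Orthonormal 2-D Haar transform and a translation-invariant
# soft-thresholding denoiser built on it.  This is the package's
# self-contained Gaussian denoiser: it serves as the guide estimator for
# the residual-learning denoiser and as the classic wavelet-AMP baseline.

max_dyadic_levels <- function(n) {
  lev <- 0L
  while (n %% 2L == 0L && n > 1L) { n <- n %/% 2L; lev <- lev + 1L }
  lev
}

haar_step_fwd <- function(x) {
  # one analysis level along rows then columns of the top-left block
  n <- nrow(x); m <- ncol(x)
  odd <- seq(1, n, by = 2); even <- odd + 1
  tmp <- rbind((x[odd, , drop = FALSE] + x[even, , drop = FALSE]) / sqrt(2),
               (x[odd, , drop = FALSE] - x[even, , drop = FALSE]) / sqrt(2))
  odd <- seq(1, m, by = 2); even <- odd + 1
  cbind((tmp[, odd, drop = FALSE] + tmp[, even, drop = FALSE]) / sqrt(2),
        (tmp[, odd, drop = FALSE] - tmp[, even, drop = FALSE]) / sqrt(2))
}

haar_step_inv <- function(w) {
  n <- nrow(w); m <- ncol(w)
  h <- m %/% 2
  tmp <- matrix(0, n, m)
  a <- w[, seq_len(h), drop = FALSE]; d <- w[, h + seq_len(h), drop = FALSE]
  tmp[, seq(1, m, by = 2)] <- (a + d) / sqrt(2)
  tmp[, seq(2, m, by = 2)] <- (a - d) / sqrt(2)
  h <- n %/% 2
  out <- matrix(0, n, m)
  a <- tmp[seq_len(h), , drop = FALSE]; d <- tmp[h + seq_len(h), , drop = FALSE]
  out[seq(1, n, by = 2), ] <- (a + d) / sqrt(2)
  out[seq(2, n, by = 2), ] <- (a - d) / sqrt(2)
  out
}

#' Orthonormal 2-D Haar wavelet transform
#'
#' Multi-level separable Haar analysis/synthesis with unitary
#' normalisation (energy preserving).  Both image sides must be divisible
#' by `2^levels`; `levels` is clipped to the largest admissible depth.
#'
#' @param x real matrix (image).
#' @param levels requested decomposition depth.
#' @return `haar2d()` returns the coefficient matrix (same shape) with an
#'   attribute `"levels"`; `ihaar2d()` inverts it.
#' @export
haar2d <- function(x, levels = 4L) {
  levels <- min(levels, max_dyadic_levels(nrow(x)), max_dyadic_levels(ncol(x)))
  w <- x
  nr <- nrow(x); nc <- ncol(x)
  if (levels >= 1L) for (l in seq_len(levels)) {
    w[seq_len(nr), seq_len(nc)] <- haar_step_fwd(w[seq_len(nr), seq_len(nc), drop = FALSE])
    nr <- nr %/% 2L; nc <- nc %/% 2L
  }
  attr(w, "levels") <- levels
  w
}

#' @rdname haar2d
#' @param w coefficient matrix from `haar2d()` (or with matching layout).
#' @export
ihaar2d <- function(w, levels = attr(w, "levels")) {
  if (is.null(levels)) levels <- 4L
  levels <- min(levels, max_dyadic_levels(nrow(w)), max_dyadic_levels(ncol(w)))
  x <- w
  attr(x, "levels") <- NULL
  if (levels >= 1L) for (l in rev(seq_len(levels))) {
    nr <- nrow(w) %/% (2L^(l - 1L)); nc <- ncol(w) %/% (2L^(l - 1L))
    x[seq_len(nr), seq_len(nc)] <- haar_step_inv(x[seq_len(nr), seq_len(nc), drop = FALSE])
  }
  x
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

# fixed shift table for cycle spinning (translation invariance)
.spin_shifts <- cbind(r = c(0L, 1L, 2L, 3L, 1L, 0L, 3L, 2L),
                      c = c(0L, 2L, 1L, 3L, 0L, 1L, 2L, 3L))

shift2 <- function(x, dr, dc) {
  n <- nrow(x); m <- ncol(x)
  x[((seq_len(n) - 1 + dr) %% n) + 1, ((seq_len(m) - 1 + dc) %% m) + 1, drop = FALSE]
}

#' Wavelet soft-threshold denoiser
#'
#' Removes approximately-Gaussian noise by soft-thresholding the Haar
#' detail coefficients at `lambda_factor * sigma`, averaged over a fixed
#' set of circular shifts (cycle spinning) to suppress blocking.  The
#' coarsest approximation band is never thresholded.  With `sigma = 0`
#' the input is returned unchanged.
#'
#' @param img real matrix (image, any intensity scale).
#' @param sigma noise standard deviation in the image's intensity units.
#' @param lambda_factor threshold multiplier (default 3: the classic
#'   3-sigma rule for near-Gaussian detail coefficients).
#' @param levels decomposition depth (clipped to the image's dyadic depth).
#' @param spins number of cycle-spinning shifts (1-8; 1 = plain DWT).
#' @return denoised matrix of the same shape.
#' @export
wavelet_denoise <- function(img, sigma, lambda_factor = 3, levels = 4L, spins = 4L) {
  if (sigma < 0) stop("`sigma` must be nonnegative")
  if (sigma == 0) return(img)
  spins <- max(1L, min(as.integer(spins), nrow(.spin_shifts)))
  lambda <- lambda_factor * sigma
  acc <- matrix(0, nrow(img), ncol(img))
  for (s in seq_len(spins)) {
    dr <- .spin_shifts[s, 1]; dc <- .spin_shifts[s, 2]
    w <- haar2d(shift2(img, dr, dc), levels)
    lev <- attr(w, "levels")
    keep_r <- nrow(img) %/% (2L^lev); keep_c <- ncol(img) %/% (2L^lev)
    approx <- w[seq_len(keep_r), seq_len(keep_c), drop = FALSE]
    w <- soft_threshold(w, lambda)
    w[seq_len(keep_r), seq_len(keep_c)] <- approx
    attr(w, "levels") <- lev
    acc <- acc + shift2(ihaar2d(w), -dr, -dc)
  }
  acc / spins
}
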