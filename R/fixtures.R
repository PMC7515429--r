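# Self-contained synthetic inputs: every test and example runs without
# downloading anything.  All generators are deterministic in their seed
# and produce images on the 0-255 scale.

# standard (modified, high-contrast) Shepp-Logan ellipse table:
# intensity, semi-axes a, b, centre x0, y0, rotation phi (degrees)
.shepp_logan <- matrix(c(
   1.0, 0.69,   0.92,   0,     0,      0,
  -0.8, 0.6624, 0.874,  0,    -0.0184, 0,
  -0.2, 0.11,   0.31,   0.22,  0,    -18,
  -0.2, 0.16,   0.41,  -0.22,  0,     18,
   0.1, 0.21,   0.25,   0,     0.35,   0,
   0.1, 0.046,  0.046,  0,     0.1,    0,
   0.1, 0.046,  0.046,  0,    -0.1,    0,
   0.1, 0.046,  0.023, -0.08, -0.605,  0,
   0.1, 0.023,  0.023,  0,    -0.606,  0,
   0.1, 0.023,  0.046,  0.06, -0.605,  0), ncol = 6, byrow = TRUE)

#' Shepp-Logan head phantom
#'
#' The classic piecewise-constant ellipse phantom (modified high-contrast
#' intensities), rendered at `n x n` and scaled to the 0-255 range.
#'
#' @param n image side in pixels.
#' @return `n x n` matrix in [0, 255].
#' @export
make_phantom <- function(n) {
  xs <- seq(-1, 1, length.out = n)
  X <- matrix(rep(xs, each = n), n, n)    # column coordinate
  Y <- matrix(rep(rev(xs), n), n, n)      # row coordinate (top = +1)
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(.shepp_logan))) {
    e <- .shepp_logan[i, ]
    phi <- e[6] * pi / 180
    xr <- (X - e[4]) * cos(phi) + (Y - e[5]) * sin(phi)
    yr <- -(X - e[4]) * sin(phi) + (Y - e[5]) * cos(phi)
    img <- img + e[1] * ((xr / e[2])^2 + (yr / e[3])^2 <= 1)
  }
  img <- pmin(pmax(img, 0), 1)
  img * 255
}

#' Self-similar textured test image
#'
#' Tiles a seeded random `tile_size x tile_size` texture across an
#' `n x n` canvas and perturbs each tile by a scalar intensity jitter, so
#' patch groups are near-low-rank (exactly rank-deficient when
#' `jitter = 0`).  Emulates the repeated-texture structure that nonlocal
#' methods exploit in natural images.
#'
#' @param n image side (need not be a multiple of `tile_size`).
#' @param tile_size tile side in pixels.
#' @param jitter standard deviation of the per-tile intensity offset.
#' @param seed integer seed.
#' @return `n x n` matrix in [0, 255].
#' @export
make_selfsimilar_image <- function(n, tile_size = 6L, jitter = 0, seed = 1L) {
  p <- as.integer(tile_size)
  with_seed(seed, {
    tile <- matrix(runif(p * p, 40, 215), p, p)
    reps <- ceiling(n / p)
    img <- matrix(0, reps * p, reps * p)
    for (i in seq_len(reps)) for (j in seq_len(reps)) {
      off <- if (jitter > 0) rnorm(1, sd = jitter) else 0
      img[(i - 1) * p + 1:p, (j - 1) * p + 1:p] <- tile + off
    }
    pmin(pmax(img[1:n, 1:n, drop = FALSE], 0), 255)
  })
}

#' Sparse coefficient vector
#'
#' `k` nonzeros at seeded positions with standard normal amplitudes.
#'
#' @param n length.
#' @param k number of nonzeros (`0 <= k <= n`).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
make_sparse_signal <- function(n, k, seed = 1L) {
  if (k > n || k < 0) stop("`k` must lie in [0, n]")
  x <- numeric(n)
  if (k > 0) with_seed(seed, {
    pos <- sample.int(n, k)
    x[pos] <- rnorm(k)
  })
  x
}

#' Wavelet-sparse synthetic image
#'
#' Places `k` seeded nonzero coefficients (amplitude-scaled standard
#' normals) in the orthonormal Haar domain and inverts the transform:
#' the result is exactly `k`-sparse in the basis that the wavelet
#' baseline denoiser thresholds, the classic sparse-recovery test input.
#'
#' @param n image side (power of two recommended).
#' @param k number of nonzero wavelet coefficients.
#' @param seed integer seed.
#' @param amplitude scale of the nonzero coefficients.
#' @param levels Haar decomposition depth.
#' @return `n x n` matrix (not clipped; scale set by `amplitude`).
#' @export
make_wavelet_sparse_image <- function(n, k, seed = 1L, amplitude = 100,
                                      levels = 4L) {
  w <- matrix(make_sparse_signal(n * n, k, seed) * amplitude, n, n)
  attr(w, "levels") <- min(levels, max_dyadic_levels(n))
  ihaar2d(w)
}

#' Low-rank matrix with optional noise
#'
#' `U V' + noise` where `U` is `M x rank`, `V` is `N x rank` with seeded
#' standard normal entries: exactly `rank` nonzero singular values before
#' noise.
#'
#' @param M,N dimensions.
#' @param rank target rank (`<= min(M, N)`).
#' @param noise_std standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @return `M x N` matrix.
#' @export
make_lowrank_matrix <- function(M, N, rank, noise_std = 0, seed = 1L) {
  if (rank > min(M, N) || rank < 0) stop("`rank` must lie in [0, min(M, N)]")
  with_seed(seed, {
    X <- if (rank > 0) {
      matrix(rnorm(M * rank), M, rank) %*% t(matrix(rnorm(N * rank), N, rank))
    } else matrix(0, M, N)
    if (noise_std > 0) X <- X + matrix(rnorm(M * N, sd = noise_std), M, N)
    X
  })
}
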