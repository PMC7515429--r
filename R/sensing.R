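# Partial-Fourier sensing: variable-density k-space masks, the unitary
# measurement operator A and its adjoint, and measurement noise.

#' Generate a variable-density Fourier sampling mask
#'
#' Draws a boolean k-space sampling pattern that is dense at low spatial
#' frequencies and sparse at high ones, the standard acquisition model for
#' compressive-sensing MRI.  A fully sampled square centred on DC holds
#' `center_fraction` of the sampling budget; the remaining locations are
#' drawn without replacement with probability proportional to
#' `(1 + r/r0)^(-decay)`, where `r` is the radial distance from DC (in
#' fftshifted coordinates, so DC sits at the array centre).
#'
#' @param shape integer vector `c(rows, cols)` in pixels.
#' @param ratio sampling ratio m/n in (0, 1]: the fraction of Fourier
#'   coefficients acquired.  The mask has exactly `round(ratio * rows * cols)`
#'   `TRUE` entries.
#' @param center_fraction fraction of the sampling *budget* placed in the
#'   fully sampled central square, in `[0, 1]`.
#' @param decay positive exponent of the polynomial density fall-off.
#' @param r0 radial scale of the fall-off, in frequency pixels; defaults to
#'   `min(shape)/16`.
#' @param seed integer seed; the mask is a deterministic function of
#'   `(shape, ratio, center_fraction, decay, r0, seed)`.
#' @return An object of class `"sampling_mask"`: a list with `sampled`
#'   (logical `rows x cols` matrix in fftshifted layout, centre = DC),
#'   `shape`, `ratio`, `center_fraction`, `decay`, `r0`, `seed`.
#' @examples
#' m <- generate_vd_mask(c(64, 64), 0.2, seed = 1)
#' sum(m$sampled)  # exactly round(0.2 * 64 * 64) = 819
#' @export
generate_vd_mask <- function(shape, ratio, center_fraction = 0.3,
                             decay = 3, r0 = NULL, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be two positive integers")
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1)
    stop("`ratio` must lie in (0, 1]")
  if (center_fraction < 0 || center_fraction > 1)
    stop("`center_fraction` must lie in [0, 1]")
  if (decay <= 0) stop("`decay` must be positive")
  rows <- shape[1]; cols <- shape[2]
  n <- rows * cols
  k <- round(ratio * n)
  if (k < 1) stop("sampling budget is smaller than one coefficient")
  if (is.null(r0)) r0 <- min(shape) / 16

  sampled <- matrix(FALSE, rows, cols)
  dc <- c(rows %/% 2L + 1L, cols %/% 2L + 1L)  # DC after fftshift

  if (k >= n) {
    sampled[] <- TRUE
  } else {
    # fully sampled centre square (odd side, centred on DC)
    side <- floor(sqrt(center_fraction * k))
    if (side %% 2 == 0) side <- side - 1
    side <- max(side, 1)
    side <- min(side, 2 * min(dc[1] - 1, rows - dc[1], dc[2] - 1, cols - dc[2]) + 1)
    hr <- (side - 1) %/% 2
    ri <- (dc[1] - hr):(dc[1] + hr)
    ci <- (dc[2] - hr):(dc[2] + hr)
    sampled[ri, ci] <- TRUE
    n_center <- sum(sampled)
    remaining <- k - n_center
    if (remaining < 0) {  # degenerate tiny budgets: keep DC only
      sampled[] <- FALSE
      sampled[dc[1], dc[2]] <- TRUE
      remaining <- k - 1
    }
    if (remaining > 0) {
      r_row <- (seq_len(rows) - dc[1])
      r_col <- (seq_len(cols) - dc[2])
      rad <- sqrt(outer(r_row^2, r_col^2, `+`))
      prob <- (1 + rad / r0)^(-decay)
      cand <- which(!sampled)
      pick <- with_seed(seed, sample(cand, remaining, prob = prob[cand]))
      sampled[pick] <- TRUE
    }
  }

  structure(list(sampled = sampled, shape = shape, ratio = ratio,
                 center_fraction = center_fraction, decay = decay,
                 r0 = r0, seed = as.integer(seed)),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("k-space sampling mask: %d x %d, %d/%d coefficients (ratio %.4f)\n",
              x$shape[1], x$shape[2], sum(x$sampled),
              prod(x$shape), sum(x$sampled) / prod(x$shape)))
  invisible(x)
}

fftshift2 <- function(x) {
  r <- nrow(x); c <- ncol(x)
  x[c((r %/% 2 + 1):r, seq_len(r %/% 2)),
    c((c %/% 2 + 1):c, seq_len(c %/% 2)), drop = FALSE]
}

ifftshift2 <- function(x) {
  r <- nrow(x); c <- ncol(x)
  x[c((r - r %/% 2 + 1):r, seq_len(r - r %/% 2)),
    c((c - c %/% 2 + 1):c, seq_len(c - c %/% 2)), drop = FALSE]
}

#' Construct the partial-Fourier measurement operator
#'
#' Wraps a [generate_vd_mask()] mask into the measurement system
#' `y = A x + w`, where `A` selects rows of the unitary (symmetrically
#' normalised) 2-D discrete Fourier transform.  Because the DFT is unitary
#' and rows are merely selected, `A A* = I` on measurement space and
#' `A* A` is an orthogonal projection in image space.
#'
#' Measurement vectors are ordered column-major over the fftshifted
#' (centre = DC) frequency grid; this scan order is fixed so vectors are
#' portable across runs and platforms.
#'
#' @param mask a `"sampling_mask"`.
#' @return An object of class `"fourier_operator"` with fields `mask`,
#'   `m` (number of measurements) and `n` (number of pixels).
#' @seealso [cs_forward()], [cs_adjoint()]
#' @export
fourier_operator <- function(mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  structure(list(mask = mask, m = sum(mask$sampled), n = prod(mask$shape)),
            class = "fourier_operator")
}

#' @export
print.fourier_operator <- function(x, ...) {
  cat(sprintf("partial-Fourier operator A: %d measurements of %d pixels (ratio %.4f)\n",
              x$m, x$n, x$m / x$n))
  invisible(x)
}

#' Apply the forward measurement operator
#'
#' Computes `A x`: the unitary 2-D DFT of the image restricted to the
#' sampled k-space locations (column-major over the fftshifted grid).
#'
#' @param op a `"fourier_operator"`.
#' @param image real (or complex) matrix matching the mask shape.
#' @return complex vector of length `op$m`.
#' @export
cs_forward <- function(op, image) {
  stopifnot(inherits(op, "fourier_operator"))
  if (!identical(dim(image), as.integer(op$mask$shape)))
    stop_dim("image shape does not match the sampling mask")
  f <- stats::fft(image) / sqrt(op$n)
  fftshift2(f)[op$mask$sampled]
}

#' Apply the adjoint (zero-filled inverse) operator
#'
#' Computes `A* y`: scatter the measurement vector back to its k-space
#' locations (zeros elsewhere) and apply the unitary inverse 2-D DFT.
#' Satisfies the adjoint identity `<A x, y> == <x, A* y>`.
#'
#' @param op a `"fourier_operator"`.
#' @param meas complex vector of length `op$m`.
#' @return complex matrix of the mask shape.
#' @export
cs_adjoint <- function(op, meas) {
  stopifnot(inherits(op, "fourier_operator"))
  if (length(meas) != op$m)
    stop_dim("measurement length does not match the mask")
  fs <- matrix(0 + 0i, op$mask$shape[1], op$mask$shape[2])
  fs[op$mask$sampled] <- meas
  stats::fft(ifftshift2(fs), inverse = TRUE) / sqrt(op$n)
}

#' Add white Gaussian measurement noise
#'
#' Adds complex AWGN to a measurement vector.  `sigma` is quoted on the
#' image-intensity (0-255) scale: real and imaginary parts each receive
#' variance `sigma^2 / 2`, so the total per-coefficient variance is
#' `sigma^2` and, under the unitary DFT, the image-domain equivalent noise
#' has standard deviation `sigma`.
#'
#' @param meas complex measurement vector.
#' @param sigma noise standard deviation (image-intensity units), `>= 0`.
#' @param seed integer seed; identical `(meas, sigma, seed)` give
#'   bit-identical output.
#' @return complex vector of the same length.
#' @export
add_measurement_noise <- function(meas, sigma, seed = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a nonnegative scalar")
  if (sigma == 0) return(meas)
  m <- length(meas)
  with_seed(seed, {
    meas + complex(real = rnorm(m, sd = sigma / sqrt(2)),
                   imaginary = rnorm(m, sd = sigma / sqrt(2)))
  })
}

#' Save / load a sampling mask as portable text
#'
#' The boolean grid is stored as a plain 0/1 text raster next to a JSON
#' sidecar carrying `{shape, ratio, seed, center_fraction, decay, r0}`.
#'
#' @param mask a `"sampling_mask"`.
#' @param path file stem; writes `<path>.txt` and `<path>.json`.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns the
#'   reconstructed `"sampling_mask"`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  utils::write.table(mask$sampled * 1L, paste0(path, ".txt"),
                     row.names = FALSE, col.names = FALSE)
  meta <- mask[c("shape", "ratio", "center_fraction", "decay", "r0", "seed")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- as.matrix(utils::read.table(paste0(path, ".txt")))
  dimnames(grid) <- NULL
  structure(list(sampled = grid == 1L, shape = as.integer(meta$shape),
                 ratio = meta$ratio, center_fraction = meta$center_fraction,
                 decay = meta$decay, r0 = meta$r0, seed = as.integer(meta$seed)),
            class = "sampling_mask")
}
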