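# Independent oracles used across the suite.  These deliberately avoid
# the code paths they check: the nuclear-norm proximal problem is solved
# through the smooth variational factorisation of the nuclear norm, the
# partial DFT through explicit O(n^2) summation, and block matching
# through an exhaustive whole-image scan in plain R.

rel_err <- function(a, b) norm(a - b, "F") / norm(b, "F")

# argmin_L ||H - L||_F^2 + lambda ||L||_*  via  ||L||_* =
# min_{L = P Q'} (||P||_F^2 + ||Q||_F^2) / 2  (smooth, solved by L-BFGS
# with random restarts; every local minimum of this program is global)
prox_nuclear_oracle <- function(H, lambda, restarts = 3, seed = 1) {
  n <- nrow(H); m <- ncol(H); r <- min(n, m)
  obj <- function(v) {
    P <- matrix(v[1:(n * r)], n, r); Q <- matrix(v[-(1:(n * r))], m, r)
    E <- H - P %*% t(Q)
    sum(E^2) + lambda / 2 * (sum(P^2) + sum(Q^2))
  }
  grd <- function(v) {
    P <- matrix(v[1:(n * r)], n, r); Q <- matrix(v[-(1:(n * r))], m, r)
    E <- H - P %*% t(Q)
    c(as.vector(-2 * E %*% Q + lambda * P),
      as.vector(-2 * t(E) %*% P + lambda * Q))
  }
  best <- NULL; bestf <- Inf
  set.seed(seed)
  for (s in seq_len(restarts)) {
    v <- rnorm(n * r + m * r, sd = sqrt(sqrt(sum(H^2) / r) + 1e-3))
    for (rep in 1:2)
      v <- optim(v, obj, grd, method = "L-BFGS-B",
                 control = list(maxit = 10000, factr = 1))$par
    if (obj(v) < bestf) { bestf <- obj(v); best <- v }
  }
  P <- matrix(best[1:(n * r)], n, r); Q <- matrix(best[-(1:(n * r))], m, r)
  P %*% t(Q)
}

# exhaustive nearest-patch search over the whole image, plain R
brute_block_match <- function(image, ref, p, N) {
  rows <- nrow(image); cols <- ncol(image)
  refv <- as.vector(image[(ref[1] + 1):(ref[1] + p), (ref[2] + 1):(ref[2] + p)])
  cand <- expand.grid(col = 0:(cols - p), row = 0:(rows - p))[, 2:1]  # row-major
  d2 <- apply(cand, 1, function(rc) {
    v <- as.vector(image[(rc[1] + 1):(rc[1] + p), (rc[2] + 1):(rc[2] + p)])
    sum((v - refv)^2)
  })
  keep <- !(cand$row == ref[1] & cand$col == ref[2])
  ord <- order(d2[keep])[seq_len(N - 1)]
  rbind(ref, as.matrix(cand[keep, ][ord, ]))
}

# direct O(n^2) unitary 2-D DFT restricted to the mask, fftshifted layout,
# column-major scan order — written out as explicit sums
direct_partial_dft <- function(image, mask) {
  R <- nrow(image); C <- ncol(image)
  F <- matrix(0 + 0i, R, C)
  for (k in 0:(R - 1)) for (l in 0:(C - 1)) {
    ph <- outer(0:(R - 1) * k / R, 0:(C - 1) * l / C, `+`)
    F[k + 1, l + 1] <- sum(image * exp(-2i * pi * ph)) / sqrt(R * C)
  }
  Fs <- F[c((R %/% 2 + 1):R, 1:(R %/% 2)), c((C %/% 2 + 1):C, 1:(C %/% 2))]
  Fs[mask$sampled]
}
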