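test_that("mask cardinality is exact and DC is always sampled", {
  shapes <- list(c(32, 32), c(64, 48), c(128, 128))
  ratios <- seq(0.05, 1, length.out = 20)
  for (sh in shapes) for (r in ratios) {
    m <- generate_vd_mask(sh, r, seed = 7)
    expect_identical(sum(m$sampled), as.integer(round(r * prod(sh))))
    dc <- c(sh[1] %/% 2 + 1, sh[2] %/% 2 + 1)
    expect_true(m$sampled[dc[1], dc[2]])
  }
  expect_true(all(generate_vd_mask(c(16, 16), 1)$sampled))
})

test_that("sampling density decreases with radial frequency", {
  counts_inner <- counts_outer <- 0
  n <- 128
  dc <- c(n %/% 2 + 1, n %/% 2 + 1)
  rad <- sqrt(outer((seq_len(n) - dc[1])^2, (seq_len(n) - dc[2])^2, `+`))
  inner <- rad <= 8
  outer_ann <- rad > 56 & rad <= 64
  for (s in 1:200) {
    m <- generate_vd_mask(c(n, n), 0.2, seed = s)
    counts_inner <- counts_inner + mean(m$sampled[inner])
    counts_outer <- counts_outer + mean(m$sampled[outer_ann])
  }
  expect_gt(counts_inner / 200, counts_outer / 200)
  # full radial profile is non-increasing on average across annuli
  prof <- sapply(1:8, function(k) {
    ann <- rad > (k - 1) * 8 & rad <= k * 8
    mean(sapply(1:20, function(s) mean(generate_vd_mask(c(n, n), 0.2, seed = s)$sampled[ann])))
  })
  expect_true(all(diff(prof) <= 1e-12))
})

test_that("mask generation validates parameters and is seed-deterministic", {
  expect_error(generate_vd_mask(c(32, 32), 0), "ratio")
  expect_error(generate_vd_mask(c(32, 32), 1.2), "ratio")
  expect_error(generate_vd_mask(c(32, 32), 0.2, center_fraction = 1.5), "center_fraction")
  expect_error(generate_vd_mask(c(2, 2), 0.01), "budget")
  m1 <- generate_vd_mask(c(64, 64), 0.25, seed = 13)
  m2 <- generate_vd_mask(c(64, 64), 0.25, seed = 13)
  expect_identical(m1$sampled, m2$sampled)
  m3 <- generate_vd_mask(c(64, 64), 0.25, seed = 14)
  expect_false(identical(m1$sampled, m3$sampled))
})

test_that("forward operator matches a direct DFT summation oracle", {
  set.seed(4)
  mask <- generate_vd_mask(c(12, 10), 0.4, seed = 2)
  op <- fourier_operator(mask)
  img <- matrix(runif(120, 0, 255), 12, 10)
  expect_lt(max(Mod(cs_forward(op, img) - direct_partial_dft(img, mask))), 1e-9)
})

test_that("unitarity, adjointness and projection identities hold", {
  set.seed(11)
  full <- fourier_operator(generate_vd_mask(c(32, 32), 1))
  x <- matrix(rnorm(1024), 32)
  # Parseval and exact inversion at full sampling
  expect_lt(abs(sqrt(sum(Mod(cs_forward(full, x))^2)) - sqrt(sum(x^2))), 1e-10)
  expect_lt(max(Mod(cs_adjoint(full, cs_forward(full, x)) - x)), 1e-10)
  op <- fourier_operator(generate_vd_mask(c(32, 32), 0.3, seed = 5))
  # forward o adjoint is the identity on measurement space
  y <- complex(real = rnorm(op$m), imaginary = rnorm(op$m))
  expect_lt(max(Mod(cs_forward(op, cs_adjoint(op, y)) - y)), 1e-10)
  # adjoint o forward is an idempotent self-adjoint projection
  P <- function(v) cs_adjoint(op, cs_forward(op, v))
  expect_lt(max(Mod(P(P(x)) - P(x))), 1e-10)
  # adjointness identity on 50 random pairs
  for (i in 1:50) {
    a <- matrix(rnorm(1024), 32)
    b <- complex(real = rnorm(op$m), imaginary = rnorm(op$m))
    lhs <- sum(Conj(cs_forward(op, a)) * b)
    rhs <- sum(Conj(a) * cs_adjoint(op, b))
    expect_lt(Mod(lhs - rhs), 1e-10)
  }
  # norm contraction
  expect_lte(sqrt(sum(Mod(cs_forward(op, x))^2)), sqrt(sum(x^2)) + 1e-12)
})

test_that("constant and zero images transform as expected", {
  op <- fourier_operator(generate_vd_mask(c(16, 16), 1))
  y <- cs_forward(op, matrix(2.5, 16, 16))
  expect_equal(sum(Mod(y) > 1e-9), 1)          # only DC
  expect_equal(max(Mod(y)), 2.5 * 16, tolerance = 1e-12)
  expect_equal(max(Mod(cs_forward(op, matrix(0, 16, 16)))), 0)
  expect_error(cs_forward(op, matrix(0, 8, 8)), "shape")
  expect_error(cs_adjoint(op, complex(real = 1:5)), "length")
})

test_that("measurement noise has the stated variance and is reproducible", {
  m <- 1e4
  y <- complex(real = rep(0, m))
  yn <- add_measurement_noise(y, 8, seed = 21)
  v <- mean(Mod(yn)^2)
  expect_lt(abs(v - 64) / 64, 0.05)
  expect_identical(yn, add_measurement_noise(y, 8, seed = 21))
  expect_identical(add_measurement_noise(y, 0, seed = 1), y)
  expect_error(add_measurement_noise(y, -1), "sigma")
})

test_that("masks round-trip through their text representation", {
  m <- generate_vd_mask(c(24, 24), 0.3, seed = 9)
  stem <- file.path(tempdir(), "mask_rt")
  write_mask(m, stem)
  m2 <- read_mask(stem)
  expect_identical(m2$sampled, m$sampled)
  expect_equal(m2$ratio, m$ratio)
  expect_identical(m2$seed, m$seed)
})
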