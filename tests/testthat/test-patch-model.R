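test_that("exemplar grids cover the image and match the arithmetic", {
  ex <- select_exemplars(c(16, 16), 6, 5)
  expect_equal(nrow(ex), 9)
  expect_setequal(unique(ex[, 1]), c(0L, 5L, 10L))
  expect_setequal(unique(ex[, 2]), c(0L, 5L, 10L))
  ex1 <- select_exemplars(c(20, 15), 4, 1)
  expect_equal(nrow(ex1), (20 - 4 + 1) * (15 - 4 + 1))
  # every pixel covered by at least one exemplar patch
  ex2 <- select_exemplars(c(128, 128), 6, 5)
  cov <- matrix(0L, 128, 128)
  for (i in seq_len(nrow(ex2)))
    cov[ex2[i, 1] + 1:6, ex2[i, 2] + 1:6] <- 1L
  expect_true(all(cov == 1L))
  expect_error(select_exemplars(c(4, 4), 6), "patch_size")
})

test_that("block matching equals the exhaustive brute-force oracle", {
  set.seed(31)
  img <- matrix(runif(32 * 32, 0, 255), 32)
  for (ref in list(c(0L, 0L), c(10L, 7L), c(26L, 26L))) {
    got <- block_match(img, ref, 6, window = 64, num_similar = 12)
    want <- brute_block_match(img, ref, 6, 12)
    d_got <- attr(got, "distances")
    expect_equal(unname(got[, 1]), unname(want[, 1]))
    expect_equal(unname(got[, 2]), unname(want[, 2]))
    expect_true(all(diff(d_got[-1]) >= -1e-12))
  }
})

test_that("block matching ties break by row-major scan order", {
  img <- matrix(7, 20, 20)
  got <- block_match(img, c(5L, 5L), 4, window = 12, num_similar = 5)
  expect_equal(unname(got[1, ]), c(5L, 5L))
  # candidates in the clipped window start at (1,1); first four non-ref
  # corners in row-major order
  expect_equal(unname(got[2:5, ]),
               rbind(c(1L, 1L), c(1L, 2L), c(1L, 3L), c(1L, 4L)))
  expect_true(all(attr(got, "distances") == 0))
})

test_that("a p-periodic image yields exact duplicate matches", {
  img <- make_selfsimilar_image(60, 6, jitter = 0, seed = 2)
  g <- patch_group(img, c(12L, 18L), 6, window = 31, num_similar = 10)
  expect_true(all(abs(g$matrix - g$matrix[, 1]) < 1e-12))
  expect_equal(qr(g$matrix)$rank, 1)
})

test_that("group matrices extract patches exactly and round-trip", {
  set.seed(8)
  img <- matrix(rnorm(30 * 30), 30)
  block <- img[11:16, 21:26]
  m <- group_to_matrix(img, rbind(c(10L, 20L)), 6)
  expect_equal(dim(m), c(36L, 1L))
  expect_equal(m[, 1], as.vector(block))   # column-major vectorisation
  reps <- matrix(rep(c(3L, 4L), each = 5), ncol = 2)
  expect_equal(qr(group_to_matrix(img, reps, 6))$rank, 1)
  coords <- rbind(c(0L, 0L), c(7L, 13L), c(24L, 24L))
  M <- group_to_matrix(img, coords, 6)
  for (j in 1:3) {
    patch <- matrix(M[, j], 6, 6)
    expect_equal(patch, img[coords[j, 1] + 1:6, coords[j, 2] + 1:6])
  }
  expect_error(group_to_matrix(img, rbind(c(28L, 0L)), 6), "outside")
})

test_that("extract then aggregate reproduces the image exactly", {
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(runif(40 * 40, 0, 255), 40)
    ex <- select_exemplars(c(40, 40), 6, 5)
    groups <- lapply(seq_len(nrow(ex)), function(i)
      patch_group(img, ex[i, ], 6, window = 31, num_similar = 8))
    out <- aggregate_groups(groups, c(40, 40))
    expect_lt(max(abs(out - img)), 1e-12)
  }
})

test_that("aggregation averages overlaps and pastes single patches", {
  g1 <- structure(list(ref_coord = c(0L, 0L),
                       member_coords = rbind(c(0L, 0L)),
                       matrix = matrix(2, 16, 1), patch_size = 4L),
                  class = "patch_group")
  g2 <- structure(list(ref_coord = c(0L, 2L),
                       member_coords = rbind(c(0L, 2L)),
                       matrix = matrix(6, 16, 1), patch_size = 4L),
                  class = "patch_group")
  expect_error(aggregate_groups(list(g1), c(4, 6)), "no patch")
  out <- aggregate_groups(list(g1, g2), c(4, 6))
  expect_equal(out[, 1:2], matrix(2, 4, 2))
  expect_equal(out[, 3:4], matrix(4, 4, 2))   # (2 + 6) / 2 on the overlap
  expect_equal(out[, 5:6], matrix(6, 4, 2))
  # single patch pastes verbatim
  set.seed(1)
  v <- rnorm(16)
  g3 <- structure(list(ref_coord = c(0L, 0L),
                       member_coords = rbind(c(0L, 0L)),
                       matrix = matrix(v, 16, 1), patch_size = 4L),
                  class = "patch_group")
  expect_equal(as.vector(aggregate_groups(list(g3), c(4, 4))), v)
})

test_that("the C++ matching fast path agrees with the R reference", {
  set.seed(17)
  img <- matrix(runif(48 * 48, 0, 255), 48)
  ex <- select_exemplars(c(48, 48), 6, 7)
  cc <- rldamp:::cpp_block_match_all(img, ex, 6L, 31L, 10L)
  for (i in seq_len(nrow(ex))) {
    rr <- block_match(img, ex[i, ], 6, window = 31, num_similar = 10)
    expect_equal(unname(cc[(i - 1) * 10 + 1:10, ]), unname(rr[, ]))
  }
})
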