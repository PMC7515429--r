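# Nonlocal self-similarity machinery: exemplar grids, block matching,
# patch-group matrices and overlap-averaged aggregation.
#
# Conventions (used everywhere): coordinates are 0-based (row, col)
# top-left corners of p x p patches; patches are vectorised column-major,
# so a group matrix is p^2 x N with column j the patch at coords[j, ].

#' Select exemplar patch positions on a regular grid
#'
#' Top-left corners every `stride` pixels in both directions, always
#' including the last valid corner `dim - p`, so that every pixel of the
#' image is covered by at least one exemplar patch.
#'
#' @param shape image dimensions `c(rows, cols)`.
#' @param patch_size patch side `p` (patches are `p x p`).
#' @param stride grid spacing in pixels (default 5).
#' @return integer matrix with columns `row`, `col` (0-based corners),
#'   ordered row-major over the grid.
#' @export
select_exemplars <- function(shape, patch_size, stride = 5L) {
  shape <- as.integer(shape); p <- as.integer(patch_size)
  if (p > min(shape)) stop("patch_size exceeds the image side")
  if (stride < 1L) stop("stride must be >= 1")
  axis <- function(n) {
    last <- n - p
    unique(c(seq(0L, last, by = stride), last))
  }
  rr <- axis(shape[1]); cc <- axis(shape[2])
  out <- cbind(row = rep(rr, each = length(cc)), col = rep(cc, times = length(rr)))
  storage.mode(out) <- "integer"
  out
}

# 0-based candidate corner range for a window of F x F pixels centred on
# the exemplar patch, clipped to the image
window_range <- function(ref, p, window, n) {
  half <- (window - p) %/% 2L
  lo <- max(0L, ref - half)
  hi <- min(n - p, ref - half + (window - p))
  lo:hi
}

extract_patch_vec <- function(image, r, c, p) {
  as.vector(image[(r + 1):(r + p), (c + 1):(c + p)])
}

#' Find the most similar patches to an exemplar (block matching)
#'
#' Exhaustively scans the `window x window` pixel neighbourhood centred on
#' the exemplar patch (clipped at image borders) and returns the
#' `num_similar` candidate corners with smallest Euclidean distance to the
#' exemplar patch.  The exemplar is always first; remaining candidates are
#' ordered by (distance, row-major scan order), so ties are deterministic.
#' If the window holds fewer than `num_similar` candidates it is expanded
#' to the whole image.
#'
#' @param image real matrix.
#' @param ref_coord 0-based `c(row, col)` corner of the exemplar.
#' @param patch_size patch side `p`.
#' @param window search window side in pixels (`>= p`); default 31.
#' @param num_similar number of patches `N` to return (exemplar included).
#' @return integer `N x 2` matrix of corners with attribute
#'   `"distances"` (non-decreasing after the first entry).
#' @export
block_match <- function(image, ref_coord, patch_size, window = 31L,
                        num_similar = 36L) {
  p <- as.integer(patch_size)
  if (window < p) stop("window must be at least patch_size")
  ref <- as.integer(ref_coord)
  rows <- nrow(image); cols <- ncol(image)
  cand <- function(win) {
    rr <- window_range(ref[1], p, win, rows)
    cc <- window_range(ref[2], p, win, cols)
    # row-major scan order over candidates
    cbind(row = rep(rr, each = length(cc)), col = rep(cc, times = length(rr)))
  }
  cd <- cand(as.integer(window))
  if (nrow(cd) < num_similar) cd <- cand(max(rows, cols) + p)
  if (nrow(cd) < num_similar)
    stop("fewer candidate patches than `num_similar` even over the whole image")
  refv <- extract_patch_vec(image, ref[1], ref[2], p)
  d2 <- vapply(seq_len(nrow(cd)), function(i) {
    v <- extract_patch_vec(image, cd[i, 1], cd[i, 2], p)
    sum((v - refv)^2)
  }, numeric(1))
  is_ref <- cd[, 1] == ref[1] & cd[, 2] == ref[2]
  others <- which(!is_ref)
  ord <- others[order(d2[others])]          # stable: ties keep scan order
  take <- ord[seq_len(num_similar - 1L)]
  coords <- rbind(ref, cd[take, , drop = FALSE])
  dimnames(coords) <- list(NULL, c("row", "col"))
  storage.mode(coords) <- "integer"
  attr(coords, "distances") <- sqrt(c(0, d2[take]))
  coords
}

#' Stack patches into a group matrix
#'
#' Column `j` is the column-major vectorisation of the `p x p` patch whose
#' 0-based top-left corner is `coords[j, ]`.  Pure extraction: no
#' normalisation or centering.
#'
#' @param image real matrix.
#' @param coords integer `N x 2` matrix of 0-based corners.
#' @param patch_size patch side `p`.
#' @return `p^2 x N` matrix.
#' @export
group_to_matrix <- function(image, coords, patch_size) {
  p <- as.integer(patch_size)
  coords <- matrix(as.integer(coords), ncol = 2)
  if (any(coords < 0L) || any(coords[, 1] > nrow(image) - p) ||
      any(coords[, 2] > ncol(image) - p))
    stop_dim("patch coordinates fall outside the image")
  vapply(seq_len(nrow(coords)),
         function(j) extract_patch_vec(image, coords[j, 1], coords[j, 2], p),
         numeric(p * p))
}

#' Construct a patch group
#'
#' Convenience constructor tying together [block_match()] and
#' [group_to_matrix()] into the `"patch_group"` container used by the
#' group denoiser.
#'
#' @inheritParams block_match
#' @return object of class `"patch_group"`: list with `ref_coord`,
#'   `member_coords`, `matrix` (`p^2 x N`), `patch_size`.
#' @export
patch_group <- function(image, ref_coord, patch_size, window = 31L,
                        num_similar = 36L) {
  coords <- block_match(image, ref_coord, patch_size, window, num_similar)
  structure(list(ref_coord = as.integer(ref_coord),
                 member_coords = coords,
                 matrix = group_to_matrix(image, coords, patch_size),
                 patch_size = as.integer(patch_size)),
            class = "patch_group")
}

#' Aggregate (possibly modified) patch groups back into an image
#'
#' Every output pixel is the average of all patch values covering it.
#' A pixel covered by no patch signals a mis-configured exemplar grid and
#' raises an error.
#'
#' @param groups list of `"patch_group"` objects (their `matrix` fields may
#'   have been modified, e.g. by [denoise_group()]).
#' @param shape output image dimensions.
#' @return real matrix of dimension `shape`.
#' @export
aggregate_groups <- function(groups, shape) {
  acc <- matrix(0, shape[1], shape[2])
  cnt <- matrix(0, shape[1], shape[2])
  for (g in groups) {
    p <- g$patch_size
    for (j in seq_len(ncol(g$matrix))) {
      r <- g$member_coords[j, 1]; c <- g$member_coords[j, 2]
      ri <- (r + 1):(r + p); ci <- (c + 1):(c + p)
      acc[ri, ci] <- acc[ri, ci] + matrix(g$matrix[, j], p, p)
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
  }
  if (any(cnt == 0))
    stop("aggregation found pixels covered by no patch; check the exemplar grid")
  acc / cnt
}
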