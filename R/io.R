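# Reading and writing 8-bit grayscale images.  Internal computation is
# always floating point on the 0-255 scale.

#' Read / write grayscale images
#'
#' `read_image()` accepts PNG (via the png package) or plain-text PGM
#' (P2) files and returns a numeric matrix on the 0-255 scale (color PNGs
#' are converted to luma by channel averaging).  `write_image()` writes
#' 8-bit grayscale PNG or PGM depending on the file extension.
#'
#' @param path file path (`.png`, `.pgm`).
#' @return `read_image()`: numeric matrix in [0, 255].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
    return(a * 255)
  }
  if (ext == "pgm") {
    txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    if (txt[1] != "P2") stop("only plain-text (P2) PGM is supported")
    w <- as.integer(txt[2]); h <- as.integer(txt[3]); mx <- as.numeric(txt[4])
    vals <- as.numeric(txt[-(1:4)])
    return(matrix(vals, h, w, byrow = TRUE) * (255 / mx))
  }
  stop(sprintf("unsupported image format '%s'", ext))
}

#' @rdname read_image
#' @param img numeric matrix on the 0-255 scale (clipped and rounded).
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  v <- round(pmin(pmax(img, 0), 255))
  if (ext == "png") {
    png::writePNG(v / 255, path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(v), nrow(v)), "255"), con)
    apply(v, 1, function(row) writeLines(paste(row, collapse = " "), con))
  } else stop(sprintf("unsupported image format '%s'", ext))
  invisible(path)
}
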