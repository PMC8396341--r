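#' Write an image to a PNG file
#'
#' Supports the two formats the pipeline emits: an `H x W x 3` array of
#' integer intensities in `[0, 255]` (8-bit RGB tile) or an `H x W` matrix of
#' values in `[0, 1]` written as 16-bit grayscale (density-map preview;
#' scaled, lossy, preview-only).
#'
#' @param image Numeric array `H x W x 3` (values 0--255) or matrix (values
#'   0--1).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  if (is.matrix(image)) {
    px <- pmin(pmax(image, 0), 1) * 65535
    pixels <- as.integer(round(t(px)))  # scanline order: row by row
    raw_png <- .png_encode(pixels, nrow(image), ncol(image), 1L, 16L)
  } else if (length(dim(image)) == 3 && dim(image)[3] == 3) {
    h <- dim(image)[1]; w <- dim(image)[2]
    px <- as.integer(pmin(pmax(round(image), 0), 255))
    dim(px) <- dim(image)
    # interleave channels per pixel, rows as scanlines
    pixels <- integer(h * w * 3)
    for (ch in 1:3) pixels[seq(ch, by = 3, length.out = h * w)] <- t(px[, , ch])
    raw_png <- .png_encode(pixels, h, w, 3L, 8L)
  } else {
    stop("image must be an H x W x 3 array or an H x W matrix", call. = FALSE)
  }
  writeBin(as.raw(raw_png), path)
  invisible(path)
}

#' Read a PNG file written by [write_png()]
#'
#' @param path PNG file path.
#' @return For RGB files, an integer `H x W x 3` array in `[0, 255]`; for
#'   16-bit grayscale, an `H x W` numeric matrix in `[0, 1]`.
#' @export
read_png <- function(path) {
  dec <- .png_decode(readBin(path, "raw", file.info(path)$size))
  h <- dec$height; w <- dec$width
  if (dec$channels == 3) {
    out <- array(0L, c(h, w, 3))
    for (ch in 1:3)
      out[, , ch] <- matrix(dec$pixels[seq(ch, by = 3, length.out = h * w)],
                            h, w, byrow = TRUE)
    out
  } else {
    scale <- if (dec$bitdepth == 16) 65535 else 255
    matrix(dec$pixels, h, w, byrow = TRUE) / scale
  }
}
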