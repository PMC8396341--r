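#' Discrete Gaussian kernel
#'
#' Evaluates \eqn{G(x, y; \sigma) = \frac{1}{2\pi\sigma^2}
#' e^{-(x^2 + y^2)/(2\sigma^2)}} at integer offsets on an `l x l` grid
#' centered on the midpoint. With `normalize = TRUE` the entries are rescaled
#' to sum to one (unit mass), so that a density map built from it integrates
#' to the object count.
#'
#' @param sigma Kernel bandwidth in pixels (> 0).
#' @param l Side length in pixels; must be odd and >= 3. Default `6*sigma+1`
#'   (rounded up to odd) covers +/- 3 sigma.
#' @param normalize Rescale entries to sum to 1 (default `TRUE`).
#' @return An `l x l` numeric matrix.
#' @examples
#' k <- gaussian_kernel(1, 7, normalize = FALSE)
#' k[4, 4]  # 1 / (2 * pi)
#' @export
gaussian_kernel <- function(sigma, l = NULL, normalize = TRUE) {
  assert_that(sigma > 0, "sigma must be positive")
  if (is.null(l)) {
    l <- ceiling(6 * sigma) + 1
    if (l %% 2 == 0) l <- l + 1
  }
  assert_that(l %% 2 == 1, "kernel side length l must be odd")
  assert_that(l >= 3, "kernel side length l must be at least 3")
  half <- (l - 1) / 2
  off <- (-half):half
  g <- exp(-off^2 / (2 * sigma^2))
  k <- outer(g, g) / (2 * pi * sigma^2)
  if (normalize) k <- k / sum(k)
  k
}

#' Build a Gaussian density-map regression target from point annotations
#'
#' Places value `d` at each annotated pixel (fractional coordinates are
#' rounded half away from zero; coincident centers add) and convolves with
#' the Gaussian kernel using zero-padded borders. With the default unit-mass
#' kernel and `d = 1`, the map mass equals the number of annotations up to
#' border truncation.
#'
#' @param annotations Data frame with 0-based pixel columns `x` (column) and
#'   `y` (row), or an `annotated_tile`.
#' @param shape Integer vector `c(height, width)`; defaults to the tile's
#'   image shape when `annotations` is an `annotated_tile`.
#' @param d Value assigned to each annotated pixel before convolution.
#' @param sigma,l Kernel parameters, see [gaussian_kernel()].
#' @param normalize Passed to [gaussian_kernel()].
#' @return An object of class `density_map`: list with `values`
#'   (`H x W` matrix), `d`, `sigma`, `l`.
#' @export
build_density_map <- function(annotations, shape = NULL, d = 1, sigma = 4,
                              l = NULL, normalize = TRUE) {
  if (inherits(annotations, "annotated_tile")) {
    if (is.null(shape)) shape <- dim(annotations$image)[1:2]
    annotations <- annotations$annotations
  }
  assert_that(!is.null(shape) && length(shape) == 2,
              "shape must be c(height, width)")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  k <- gaussian_kernel(sigma, l, normalize)
  l <- nrow(k)
  half <- (l - 1) / 2
  values <- matrix(0, H, W)
  n <- nrow(annotations)
  if (n > 0) {
    xi <- round_half_away(annotations$x)
    yi <- round_half_away(annotations$y)
    bad <- which(xi < 0 | xi > W - 1 | yi < 0 | yi > H - 1)
    if (length(bad))
      stop(sprintf("annotation %d at (%.6g, %.6g) lies outside the %dx%d image",
                   bad[1], annotations$x[bad[1]], annotations$y[bad[1]], W, H),
           call. = FALSE)
    for (i in seq_len(n)) {
      r <- yi[i] + 1; c <- xi[i] + 1
      r0 <- max(1, r - half); r1 <- min(H, r + half)
      c0 <- max(1, c - half); c1 <- min(W, c + half)
      kr <- (r0 - r + half + 1):(r1 - r + half + 1)
      kc <- (c0 - c + half + 1):(c1 - c + half + 1)
      values[r0:r1, c0:c1] <- values[r0:r1, c0:c1] + d * k[kr, kc]
    }
  }
  structure(list(values = values, d = d, sigma = sigma, l = l),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %dx%d, mass %.4f (d=%g, sigma=%g, l=%d)\n",
              nrow(x$values), ncol(x$values), sum(x$values), x$d, x$sigma, x$l))
  invisible(x)
}

#' Serialize / load a density map as a plain-text container
#'
#' The container is a TSV of the value matrix preceded by a single header
#' line `#tilmap-density d sigma l`. An optional 16-bit PNG preview (scaled
#' to the max value, lossy) can be written alongside.
#'
#' @param map A `density_map`.
#' @param path Output `.tsv` path.
#' @param preview If `TRUE`, also write `<path>.png` preview.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path, preview = FALSE) {
  con <- file(path, "w")
  writeLines(sprintf("#tilmap-density %.17g %.17g %d", map$d, map$sigma, map$l),
             con)
  close(con)
  data.table::fwrite(data.table::as.data.table(map$values), path, sep = "\t",
                     append = TRUE, col.names = FALSE)
  if (preview) {
    mx <- max(map$values)
    write_png(if (mx > 0) map$values / mx else map$values,
              paste0(path, ".png"))
  }
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path) {
  hdr <- readLines(path, n = 1)
  assert_that(startsWith(hdr, "#tilmap-density"),
              paste0("not a density-map file: ", path))
  # predicted maps carry NA metadata (no kernel was involved)
  meta <- suppressWarnings(as.numeric(strsplit(hdr, " ")[[1]][-1]))
  values <- as.matrix(data.table::fread(path, sep = "\t", skip = 1,
                                        header = FALSE))
  dimnames(values) <- NULL
  structure(list(values = values, d = meta[1], sigma = meta[2],
                 l = as.integer(meta[3])),
            class = "density_map")
}
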