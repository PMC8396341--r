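as_map_matrix <- function(map) {
  if (inherits(map, "density_map")) map$values else map
}

#' Clip negative density values to zero
#'
#' The network's identity output head can undershoot zero around background;
#' a valid density map is nonnegative.
#'
#' @param map A `density_map` or numeric matrix with finite values.
#' @return Same type as the input, with `max(x, 0)` applied elementwise.
#' @export
clip_negative <- function(map) {
  v <- as_map_matrix(map)
  if (anyNA(v) || any(!is.finite(v)))
    stop("density map contains NaN or non-finite values", call. = FALSE)
  out <- pmax(v, 0)
  if (inherits(map, "density_map")) {
    map$values <- out
    map
  } else out
}

#' Otsu threshold of a density map
#'
#' Builds a 256-bin histogram over the value range and returns the bin edge
#' maximizing the between-class variance (equivalently minimizing the
#' within-class intensity variance). Pixels strictly above the threshold are
#' foreground.
#'
#' @param map A `density_map` or numeric matrix with at least 2 distinct
#'   values.
#' @param bins Number of histogram bins (default 256, the image-processing
#'   convention).
#' @return The threshold value (numeric scalar).
#' @export
otsu_threshold <- function(map, bins = 256) {
  v <- as.numeric(as_map_matrix(map))
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("degenerate histogram: density map is constant", call. = FALSE)
  edges <- seq(lo, hi, length.out = bins + 1)
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), bins)
  counts <- tabulate(idx, bins)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  w <- cumsum(counts)                   # class-0 mass up to each cut
  m <- cumsum(counts * mids)            # class-0 first moment
  n <- w[bins]; mtot <- m[bins]
  # candidate cuts after bin t, t = 1..bins-1
  w0 <- w[-bins]; w1 <- n - w0
  mu0 <- m[-bins] / w0; mu1 <- (mtot - m[-bins]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  t <- which.max(between)
  edges[t + 1]
}

#' Split a foreground mask into labelled components via seeded watershed
#'
#' Seeds are local maxima of the density inside the mask with a minimum
#' separation of `min_seed_separation` pixels (default 8 px, one lymphocyte
#' diameter at 0.5 um/px); the watershed then floods the negated density
#' restricted to the mask. The number of output labels is at least the
#' number of 8-connected components of the mask (mask components without a
#' positive-density seed keep one label each).
#'
#' @param mask Logical or 0/1 integer matrix.
#' @param map A `density_map` or matrix aligned with `mask`.
#' @param min_seed_separation Minimum seed separation in pixels.
#' @return An object of class `labeled_mask`: list with `labels` (integer
#'   matrix, 0 = background), `n` (number of components).
#' @export
split_components <- function(mask, map, min_seed_separation = 8) {
  v <- as_map_matrix(map)
  m <- matrix(as.integer(mask != 0), nrow(v), ncol(v))
  if (!any(m == 1))
    return(structure(list(labels = matrix(0L, nrow(v), ncol(v)), n = 0L),
                     class = "labeled_mask"))
  seeds <- .local_maxima(v, m, as.integer(ceiling(min_seed_separation / 2)),
                         min_seed_separation)
  labels <- if (nrow(seeds) > 0) .watershed(v, m, seeds)
            else matrix(0L, nrow(v), ncol(v))
  # components untouched by the flood (e.g. zero-density plateaus) get
  # their own labels so labelling is a partition of the mask
  orphan <- m == 1 & labels == 0
  if (any(orphan)) {
    extra <- .cc_label(matrix(as.integer(orphan), nrow(v), ncol(v)))
    labels[orphan] <- extra[orphan] + max(labels)
  }
  structure(list(labels = labels, n = max(labels)), class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %dx%d, %d components\n",
              nrow(x$labels), ncol(x$labels), x$n))
  invisible(x)
}

#' Density-weighted centers of mass of labelled components
#'
#' @param labeled A `labeled_mask` (or plain integer label matrix).
#' @param map A `density_map` or matrix of weights; where a component's
#'   total weight is zero, the unweighted centroid is used.
#' @return Data frame with 0-based `x`, `y` (fractional pixel coordinates),
#'   `component_area` and `peak_value`, one row per component.
#' @export
centers_of_mass <- function(labeled, map) {
  labels <- if (inherits(labeled, "labeled_mask")) labeled$labels else labeled
  v <- as_map_matrix(map)
  n <- max(labels)
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      component_area = integer(0), peak_value = numeric(0)))
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1) %% nrow(labels)       # 0-based y
  cols <- (idx - 1) %/% nrow(labels)      # 0-based x
  wts <- v[idx]
  totw <- vapply(split(wts, lab), sum, 0)
  area <- vapply(split(wts, lab), length, 0L)
  peak <- vapply(split(wts, lab), max, 0)
  xs <- ys <- numeric(n)
  sx <- vapply(split(wts * cols, lab), sum, 0)
  sy <- vapply(split(wts * rows, lab), sum, 0)
  ux <- vapply(split(cols, lab), mean, 0)
  uy <- vapply(split(rows, lab), mean, 0)
  zero <- totw <= 0
  xs[!zero] <- sx[!zero] / totw[!zero]; xs[zero] <- ux[zero]
  ys[!zero] <- sy[!zero] / totw[!zero]; ys[zero] <- uy[zero]
  data.frame(x = xs, y = ys, component_area = as.integer(area),
             peak_value = peak)
}

#' Detect cell centers in a predicted density map
#'
#' The three-step postprocessing pipeline: clip negative values, Otsu
#' threshold (strictly-greater binarization), watershed split of merged
#' components, then density-weighted centers of mass. A constant map (e.g.
#' all zero after clipping) yields an empty prediction set.
#'
#' @param map A `density_map` or numeric matrix.
#' @param min_seed_separation Watershed seed separation in pixels.
#' @param min_area Components smaller than this pixel count are dropped
#'   (default 0: no area filter).
#' @return Data frame of predicted centers (`x`, `y`, 0-based, plus
#'   `component_area` and `peak_value`).
#' @export
detect <- function(map, min_seed_separation = 8, min_area = 0) {
  v <- clip_negative(as_map_matrix(map))
  if (min(v) == max(v))
    return(data.frame(x = numeric(0), y = numeric(0),
                      component_area = integer(0), peak_value = numeric(0)))
  thr <- otsu_threshold(v)
  mask <- v > thr
  lab <- split_components(mask, v, min_seed_separation)
  out <- centers_of_mass(lab, v)
  if (min_area > 0) out <- out[out$component_area >= min_area, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a prediction set to CSV
#'
#' @param predictions Data frame from [detect()].
#' @param tile_id Tile identifier recorded in the first column.
#' @param path Output CSV; appended to if it exists.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, tile_id, path) {
  df <- cbind(tile_id = tile_id, predictions)
  data.table::fwrite(df, path, append = file.exists(path))
  invisible(path)
}
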