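#' Physical geometry of a square tile
#'
#' @param side Tile side in pixels (> 0).
#' @param resolution Pixel size rho in micrometers per pixel (> 0).
#' @return Named list with `side_mm` (`side * rho * 1e-3`) and `area_mm2`
#'   (its square). A 512 px tile at 0.5 um/px has side 0.256 mm and area
#'   0.065536 mm^2.
#' @export
tile_geometry <- function(side, resolution = 0.5) {
  assert_that(side > 0, "tile side must be positive")
  assert_that(resolution > 0, "resolution must be positive")
  side_mm <- side * resolution * 1e-3
  list(side_mm = side_mm, area_mm2 = side_mm^2)
}

#' Slide-level log lymphocyte density
#'
#' The slide statistic is the natural logarithm of the mean lymphocyte
#' density over `n` regions: \eqn{L = \ln(\frac{1}{n}\sum_i c_i / A_i)},
#' with counts `c_i` and region areas `A_i` in mm^2. A zero total count
#' gives a flagged `-Inf` sentinel rather than an error.
#'
#' @param counts Nonnegative per-region counts.
#' @param areas Positive per-region areas in mm^2 (recycled if scalar).
#' @param slide_id Optional label.
#' @return An object of class `slide_density`: list with `L`, `n_regions`,
#'   `total_count`, `mean_density`, `finite` flag, `slide_id`.
#' @export
slide_density <- function(counts, areas, slide_id = NA_character_) {
  if (length(areas) == 1) areas <- rep(areas, length(counts))
  assert_that(length(counts) == length(areas),
              "counts and areas must have equal length")
  assert_that(length(counts) >= 1, "at least one region is required")
  assert_that(all(areas > 0), "all region areas must be positive")
  assert_that(all(counts >= 0), "counts must be nonnegative")
  dens <- mean(counts / areas)
  L <- if (dens > 0) log(dens) else -Inf
  structure(list(L = L, n_regions = length(counts),
                 total_count = sum(counts), mean_density = dens,
                 finite = dens > 0, slide_id = slide_id),
            class = "slide_density")
}

#' @export
print.slide_density <- function(x, ...) {
  cat(sprintf("<slide_density> %s: L = %.4f (%d cells over %d regions)\n",
              x$slide_id, x$L, x$total_count, x$n_regions))
  invisible(x)
}

#' Compare predicted and reference slide densities
#'
#' Pearson correlation with two-sided p-value between per-slide predicted
#' and reference `L` values, plus residuals (predicted minus reference) and
#' their mean (the systematic offset). Slides with non-finite `L` on either
#' side are excluded (and counted).
#'
#' @param predicted,reference Numeric vectors of per-slide `L`, aligned.
#' @return List with `r`, `p_value`, `residuals`, `mean_residual`,
#'   `n_used`, `n_excluded`.
#' @export
compare_densities <- function(predicted, reference) {
  assert_that(length(predicted) == length(reference),
              "predicted and reference must have equal length")
  keep <- is.finite(predicted) & is.finite(reference)
  x <- predicted[keep]; y <- reference[keep]
  assert_that(length(x) >= 3, "need at least 3 slides with finite densities")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: constant density vector", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  res <- x - y
  list(r = unname(ct$estimate), p_value = ct$p.value, residuals = res,
       mean_residual = mean(res), n_used = sum(keep),
       n_excluded = sum(!keep))
}

#' Slide-level densities from per-tile detection counts
#'
#' Treats every tile of a slide as one region (count = detections, area =
#' tile area), the whole-slide analogue of the hand-picked-region protocol.
#'
#' @param counts_by_tile Data frame with columns `slide_id` and `count`.
#' @param tile_side Tile side in pixels.
#' @param resolution um/pixel.
#' @return Data frame `slide_id`, `n_regions`, `total_count`, `L`.
#' @export
quantify_slides <- function(counts_by_tile, tile_side = 512,
                            resolution = 0.5) {
  area <- tile_geometry(tile_side, resolution)$area_mm2
  out <- lapply(split(counts_by_tile, counts_by_tile$slide_id), function(df) {
    sd_ <- slide_density(df$count, area, slide_id = df$slide_id[1])
    data.frame(slide_id = sd_$slide_id, n_regions = sd_$n_regions,
               total_count = sd_$total_count, L = sd_$L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
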