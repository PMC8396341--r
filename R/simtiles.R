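#' Default morphology parameters for the tile simulator
#'
#' Cells are rendered as anisotropic Gaussian-profile blobs in a DAB-brown
#' hue on a textured tissue-like background. The default blob radius of 4 px
#' corresponds to the ~4 um lymphocyte diameter at 0.5 um/pixel; the cluster
#' fraction emulates the packed T-cell clusters seen in CD3-stained tissue.
#'
#' @param radius_mean,radius_sd Mean and s.d. of the blob radius in pixels.
#' @param eccentricity_sd S.d. of the log axis-ratio of the blob (0 = round).
#' @param cluster_fraction Fraction of cells placed in packed clusters.
#' @param cluster_spread S.d. (pixels) of cell placement around a cluster seed.
#' @param background_amplitude Amplitude (intensity units, 0--255) of the
#'   low-frequency background texture.
#' @param noise_sd Per-pixel Gaussian noise s.d. (intensity units).
#' @param min_separation Minimum pairwise center distance in pixels; `0`
#'   (the default) disables the constraint, so clusters may overlap heavily.
#' @return A named list of morphology parameters.
#' @export
tile_morphology <- function(radius_mean = 4, radius_sd = 0.6,
                            eccentricity_sd = 0.25,
                            cluster_fraction = 0.3, cluster_spread = 9,
                            background_amplitude = 12, noise_sd = 3,
                            min_separation = 0) {
  list(radius_mean = radius_mean, radius_sd = radius_sd,
       eccentricity_sd = eccentricity_sd,
       cluster_fraction = cluster_fraction, cluster_spread = cluster_spread,
       background_amplitude = background_amplitude, noise_sd = noise_sd,
       min_separation = min_separation)
}

# Low-frequency texture: coarse Gaussian grid bilinearly upsampled to H x W.
texture_field <- function(height, width, amplitude, cells = 9) {
  coarse <- matrix(rnorm(cells * cells), cells, cells)
  ty <- seq(1, cells, length.out = height)
  tx <- seq(1, cells, length.out = width)
  y0 <- pmin(floor(ty), cells - 1); x0 <- pmin(floor(tx), cells - 1)
  wy <- ty - y0; wx <- tx - x0
  f <- coarse[y0, x0] * outer(1 - wy, 1 - wx) +
    coarse[y0, x0 + 1] * outer(1 - wy, wx) +
    coarse[y0 + 1, x0] * outer(wy, 1 - wx) +
    coarse[y0 + 1, x0 + 1] * outer(wy, wx)
  f * amplitude
}

# Sample n cell centers (0-based x/y) with optional clustering and minimum
# separation (dart throwing).
sample_centers <- function(n, width, height, morph) {
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0)))
  min_sep <- morph$min_separation
  n_clustered <- round(morph$cluster_fraction * n)
  n_seeds <- max(1, ceiling(n_clustered / 8))
  seeds <- cbind(runif(n_seeds, 0, width - 1), runif(n_seeds, 0, height - 1))
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  max_tries <- 4000L * max(n, 1L)
  while (length(xs) < n) {
    if (length(xs) < n_clustered) {
      s <- seeds[sample.int(n_seeds, 1), ]
      cand <- c(s[1] + rnorm(1, 0, morph$cluster_spread),
                s[2] + rnorm(1, 0, morph$cluster_spread))
    } else {
      cand <- c(runif(1, 0, width - 1), runif(1, 0, height - 1))
    }
    cand[1] <- min(max(cand[1], 0), width - 1)
    cand[2] <- min(max(cand[2], 0), height - 1)
    ok <- TRUE
    if (min_sep > 0 && length(xs)) {
      d2 <- (xs - cand[1])^2 + (ys - cand[2])^2
      ok <- all(d2 >= min_sep^2)
    }
    if (ok) {
      xs <- c(xs, cand[1]); ys <- c(ys, cand[2])
    }
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " centers with min_separation = ",
           min_sep, " in a ", width, "x", height, " tile", call. = FALSE)
  }
  data.frame(x = xs, y = ys)
}

#' Generate a synthetic annotated IHC-like tile
#'
#' Renders `n_cells` DAB-brown blobs on a textured tissue background and
#' records their exact centers as ground-truth annotations. Identical
#' `(seed, parameters)` give identical output. Coordinates are 0-based with
#' `x` = column and `y` = row, matching VIA point exports.
#'
#' @param width,height Tile dimensions in pixels (at least 64).
#' @param n_cells Number of cells to render (>= 0).
#' @param seed Integer seed; the tile is a pure function of it.
#' @param morphology Parameter set from [tile_morphology()].
#' @param slide_id Group label attached to the tile.
#' @param resolution Pixel size in micrometers (default 0.5 um/pixel).
#' @return An object of class `annotated_tile`: list with `image`
#'   (`H x W x 3` integer array, 0--255), `annotations` (data.frame `x`, `y`,
#'   0-based pixel coordinates), `slide_id`, and `resolution`.
#' @examples
#' tile <- generate_tile(64, 64, n_cells = 5, seed = 1)
#' nrow(tile$annotations)
#' @export
generate_tile <- function(width = 512, height = 512, n_cells, seed,
                          morphology = tile_morphology(),
                          slide_id = "slide-0", resolution = 0.5) {
  assert_that(width >= 64 && height >= 64,
              "width and height must be at least 64 pixels")
  assert_that(is.numeric(n_cells) && n_cells >= 0,
              "n_cells must be a nonnegative count")
  assert_that(nzchar(slide_id), "slide_id must be non-empty")
  n_cells <- as.integer(n_cells)
  morph <- utils::modifyList(tile_morphology(), morphology)
  with_seed(seed, {
    base <- c(228, 218, 204)  # pale eosin-like tissue tone
    tex <- texture_field(height, width, morph$background_amplitude)
    img <- array(0, c(height, width, 3))
    for (ch in 1:3)
      img[, , ch] <- base[ch] + tex +
        matrix(rnorm(height * width, 0, morph$noise_sd), height, width)

    ann <- sample_centers(n_cells, width, height, morph)
    brown <- c(96, 58, 25)  # DAB chromogen hue
    if (n_cells > 0) {
      for (k in seq_len(n_cells)) {
        r <- max(1.2, rnorm(1, morph$radius_mean, morph$radius_sd))
        ecc <- exp(rnorm(1, 0, morph$eccentricity_sd))
        theta <- runif(1, 0, pi)
        a <- r * ecc; b <- r / ecc
        cx <- ann$x[k]; cy <- ann$y[k]
        ext <- ceiling(3 * max(a, b))
        x0 <- max(0, floor(cx - ext)); x1 <- min(width - 1, ceiling(cx + ext))
        y0 <- max(0, floor(cy - ext)); y1 <- min(height - 1, ceiling(cy + ext))
        xs <- x0:x1; ys <- y0:y1
        dx <- outer(rep(1, length(ys)), xs - cx)
        dy <- outer(ys - cy, rep(1, length(xs)))
        u <- cos(theta) * dx + sin(theta) * dy
        v <- -sin(theta) * dx + cos(theta) * dy
        w <- exp(-0.5 * ((u / a)^2 + (v / b)^2) * 4)  # compact core
        rows <- ys + 1; cols <- xs + 1
        for (ch in 1:3)
          img[rows, cols, ch] <- img[rows, cols, ch] * (1 - w) + brown[ch] * w
      }
    }
    img <- round(pmin(pmax(img, 0), 255))
    structure(list(image = img, annotations = ann, slide_id = slide_id,
                   resolution = resolution),
              class = "annotated_tile")
  })
}

#' @export
print.annotated_tile <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<annotated_tile> %dx%d px, %d cells, slide '%s', %.2f um/px\n",
              d[2], d[1], nrow(x$annotations), x$slide_id, x$resolution))
  invisible(x)
}

#' Default per-slide lymphocyte count sampler
#'
#' Each slide draws a mean density on a log-uniform scale spanning the full
#' ordinal class range (empty tiles through >200 cells); tile counts are then
#' Poisson around the slide mean, mimicking the strong between-slide
#' heterogeneity of immune infiltration.
#'
#' @param n_tiles Number of counts to draw for one slide.
#' @return Integer vector of per-tile counts.
#' @export
default_count_sampler <- function(n_tiles) {
  lambda <- exp(runif(1, log(0.3), log(350)))
  rpois(n_tiles, lambda)
}

#' Generate a multi-slide cohort of synthetic tiles
#'
#' Builds a cohort manifest with a leakage-safe train/test split (slides,
#' never tiles, are assigned to a subset) and optional slide-grouped CV
#' folds. Tiles are stored as reproducible specifications (per-tile seeds via
#' a counter scheme on the master seed) and rendered on demand with
#' [render_tile()], so large cohorts cost no memory until drawn.
#'
#' @param n_slides Number of slides (>= 2, so a grouped split exists).
#' @param tiles_per_slide Tiles per slide.
#' @param count_sampler Function `n -> integer counts` drawing the per-tile
#'   cell counts of one slide; default [default_count_sampler()].
#' @param seed Master seed.
#' @param test_fraction Fraction of slides held out as the test set
#'   (default 1/4, giving the 3/4--1/4 split).
#' @param folds Optional number of CV folds over the training slides
#'   (grouped by slide; error if more folds than training slides).
#' @param width,height Tile dimensions passed to [generate_tile()].
#' @param morphology Morphology parameters for rendering.
#' @return An object of class `cohort`: list with `manifest` (data.frame
#'   `tile_id`, `slide_id`, `n_cells`, `seed`, `split`, `fold`), `width`,
#'   `height`, `morphology`, `seed`.
#' @examples
#' co <- generate_cohort(4, 3, seed = 1, width = 64, height = 64)
#' table(co$manifest$split)
#' @export
generate_cohort <- function(n_slides, tiles_per_slide,
                            count_sampler = default_count_sampler,
                            seed = 1, test_fraction = 0.25, folds = NULL,
                            width = 512, height = 512,
                            morphology = tile_morphology()) {
  assert_that(n_slides >= 2,
              "n_slides must be >= 2: a grouped train/test split needs at least one slide per subset")
  with_seed(seed, {
    slide_ids <- sprintf("slide-%02d", seq_len(n_slides))
    counts <- lapply(seq_len(n_slides), function(s) {
      cnt <- count_sampler(tiles_per_slide)
      assert_that(length(cnt) == tiles_per_slide && all(cnt >= 0),
                  "count_sampler must return tiles_per_slide nonnegative counts")
      as.integer(cnt)
    })
    n_test <- max(1, round(test_fraction * n_slides))
    assert_that(n_test < n_slides, "test_fraction leaves no training slides")
    test_slides <- sample(slide_ids, n_test)
    split <- ifelse(slide_ids %in% test_slides, "test", "train")
    fold <- rep(NA_integer_, n_slides)
    if (!is.null(folds)) {
      train_idx <- which(split == "train")
      assert_that(length(train_idx) >= folds, sprintf(
        "cannot form %d slide-grouped folds from %d training slides",
        folds, length(train_idx)))
      fold[sample(train_idx)] <- rep_len(seq_len(folds), length(train_idx))
    }
    manifest <- do.call(rbind, lapply(seq_len(n_slides), function(s) {
      data.frame(
        tile_id = sprintf("%s_tile%03d", slide_ids[s], seq_len(tiles_per_slide)),
        slide_id = slide_ids[s],
        n_cells = counts[[s]],
        split = split[s],
        fold = fold[s],
        stringsAsFactors = FALSE)
    }))
    manifest$seed <- derive_seed(seed, seq_len(nrow(manifest)))
    structure(list(manifest = manifest, width = width, height = height,
                   morphology = morphology, seed = seed),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<cohort> %d tiles / %d slides (%d train, %d test), %dx%d px\n",
              nrow(m), length(unique(m$slide_id)),
              sum(m$split == "train"), sum(m$split == "test"),
              x$width, x$height))
  invisible(x)
}

#' Render one tile of a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param tile_id Tile identifier from the manifest.
#' @return The [generate_tile()] result for that tile.
#' @export
render_tile <- function(cohort, tile_id) {
  row <- cohort$manifest[cohort$manifest$tile_id == tile_id, ]
  assert_that(nrow(row) == 1, paste0("unknown tile_id: ", tile_id))
  generate_tile(cohort$width, cohort$height, row$n_cells, row$seed,
                morphology = cohort$morphology, slide_id = row$slide_id)
}

#' Write a cohort to disk (PNG tiles, annotation CSV, manifest CSV)
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann_all <- list()
  for (id in cohort$manifest$tile_id) {
    tile <- render_tile(cohort, id)
    write_png(tile$image, file.path(dir, paste0(id, ".png")))
    if (nrow(tile$annotations))
      ann_all[[id]] <- data.frame(tile_id = id, tile$annotations)
  }
  ann <- if (length(ann_all)) do.call(rbind, ann_all) else
    data.frame(tile_id = character(0), x = numeric(0), y = numeric(0))
  write_annotations(ann, file.path(dir, "annotations.csv"))
  data.table::fwrite(
    cohort$manifest[, c("tile_id", "slide_id", "split", "fold")],
    file.path(dir, "manifest.csv"))
  invisible(dir)
}
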