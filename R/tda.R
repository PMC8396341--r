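# Vietoris-Rips persistent homology over Z/2 for point clouds, dimensions
# 0 and 1. H0 comes from a union-find sweep over the sorted edges (deaths
# are the merge scales, i.e. the Euclidean MST edge lengths); H1 from the
# standard boundary-matrix reduction restricted to the triangle columns,
# with edges as the row basis in filtration order. The filtration is
# diameter-based: a simplex enters at the length of its longest edge.

#' Vietoris-Rips persistence diagram of a point cloud
#'
#' @param points Numeric matrix (one point per row) or data frame.
#' @param maxdim Maximum homology dimension (0 or 1).
#' @param maxscale Filtration cutoff; default is the cloud diameter, so the
#'   complex becomes complete and all H1 features die.
#' @param digits Significant digits the pairwise distances are rounded to
#'   before filtering (default 12). This consolidates floating-point
#'   near-ties so that symmetric configurations (e.g. regular polygons)
#'   produce their exact birth/death scales.
#' @return An object of class `persistence_diagram`: data frame with
#'   columns `dimension`, `birth`, `death` (`Inf` for the one essential H0
#'   feature of a connected input). Zero-persistence pairs (`death ==
#'   birth`) in dimension >= 1 are dropped.
#' @examples
#' hexagon <- cbind(cos(seq(0, 5) * pi / 3), sin(seq(0, 5) * pi / 3))
#' vr_persistence(hexagon)
#' @export
vr_persistence <- function(points, maxdim = 1, maxscale = NULL,
                           digits = 12) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  assert_that(n >= 1, "need at least one point")
  assert_that(maxdim %in% c(0, 1), "maxdim must be 0 or 1")
  if (!is.null(maxscale))
    assert_that(maxscale > 0, "maxscale must be positive")
  if (n == 1) {
    out <- data.frame(dimension = 0L, birth = 0, death = Inf)
    class(out) <- c("persistence_diagram", "data.frame")
    return(out)
  }
  D <- signif(as.matrix(dist(pts)), digits)
  if (is.null(maxscale)) maxscale <- max(D)

  # edges sorted by (length, lexicographic) -> global filtration ranks
  ij <- which(upper.tri(D), arr.ind = TRUE)
  elen <- D[ij]
  keep <- elen <= maxscale
  ij <- ij[keep, , drop = FALSE]; elen <- elen[keep]
  ord <- order(elen, ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]; elen <- elen[ord]
  n_edges <- length(elen)

  # union-find for H0: an edge either merges two components (negative edge,
  # records a death) or closes a cycle (positive edge, may birth an H1 class)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  h0_death <- numeric(0)
  positive <- logical(n_edges)
  for (e in seq_len(n_edges)) {
    ra <- find(ij[e, 1]); rb <- find(ij[e, 2])
    if (ra == rb) {
      positive[e] <- TRUE
    } else {
      parent[ra] <- rb
      h0_death <- c(h0_death, elen[e])
    }
  }
  n_comp <- n - length(h0_death)
  diag_list <- list(data.frame(
    dimension = 0L,
    birth = 0,
    death = c(h0_death, rep(Inf, n_comp))))

  if (maxdim >= 1 && n >= 3 && n_edges > 0) {
    # triangles with diameter <= maxscale, as triples of edge ranks
    erank <- matrix(0L, n, n)
    erank[ij] <- seq_len(n_edges)
    erank <- erank + t(erank)
    tri <- utils::combn(n, 3)
    e1 <- erank[cbind(tri[1, ], tri[2, ])]
    e2 <- erank[cbind(tri[1, ], tri[3, ])]
    e3 <- erank[cbind(tri[2, ], tri[3, ])]
    ok <- e1 > 0 & e2 > 0 & e3 > 0
    cols <- rbind(e1, e2, e3)[, ok, drop = FALSE]
    if (ncol(cols)) {
      cols <- apply(cols, 2, sort)
      # filtration order: diameter (= longest edge rank), then lower faces
      o <- order(cols[3, ], cols[2, ], cols[1, ])
      cols <- cols[, o, drop = FALSE]
      low_owner <- integer(n_edges)   # edge rank -> reduced column id
      reduced <- vector("list", ncol(cols))
      pairs_b <- pairs_d <- numeric(0)
      for (t in seq_len(ncol(cols))) {
        col <- cols[, t]
        repeat {
          if (!length(col)) break
          low <- col[length(col)]
          owner <- low_owner[low]
          if (owner == 0) break
          # symmetric difference over Z/2
          other <- reduced[[owner]]
          col <- sort(c(setdiff(col, other), setdiff(other, col)))
        }
        if (length(col)) {
          low <- col[length(col)]
          low_owner[low] <- t
          reduced[[t]] <- col
          b <- elen[low]
          d <- elen[cols[3, t]]
          if (d > b) {
            pairs_b <- c(pairs_b, b)
            pairs_d <- c(pairs_d, d)
          }
        }
      }
      if (length(pairs_b))
        diag_list[[2]] <- data.frame(dimension = 1L, birth = pairs_b,
                                     death = pairs_d)
    }
  }
  out <- do.call(rbind, diag_list)
  rownames(out) <- NULL
  class(out) <- c("persistence_diagram", "data.frame")
  out
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> %d features (H0: %d, H1: %d)\n",
              nrow(x), sum(x$dimension == 0), sum(x$dimension == 1)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Betti curve of a persistence diagram
#'
#' The Betti number at scale `r` counts features with `birth <= r < death`;
#' essential features (infinite death) are counted at every scale past their
#' birth.
#'
#' @param pd A `persistence_diagram` (or data frame with `dimension`,
#'   `birth`, `death`).
#' @param grid Increasing numeric vector of scales; default 100 uniform
#'   points on `[0, 1.1 * max finite death]`.
#' @param dims Homology dimensions to tabulate.
#' @return An object of class `betti_curve`: data frame with column `scale`
#'   and one integer column `H<k>` per requested dimension.
#' @export
betti_curve <- function(pd, grid = NULL, dims = 0:1) {
  if (is.null(grid)) {
    finite <- pd$death[is.finite(pd$death)]
    top <- if (length(finite)) max(finite) * 1.1 else 1
    grid <- seq(0, top, length.out = 100)
  }
  assert_that(length(grid) > 0, "empty scale grid")
  assert_that(all(diff(grid) > 0) || length(grid) == 1,
              "scale grid must be strictly increasing")
  out <- data.frame(scale = grid)
  for (k in dims) {
    feats <- pd[pd$dimension == k, , drop = FALSE]
    out[[paste0("H", k)]] <- vapply(grid, function(r) {
      sum(feats$birth <= r & r < feats$death)
    }, 0L)
  }
  class(out) <- c("betti_curve", "data.frame")
  out
}

#' Evaluate a Betti number at a single scale
#'
#' @param pd A `persistence_diagram`.
#' @param r Filtration scale.
#' @param dim Homology dimension.
#' @return Integer count of features alive at `r`.
#' @export
betti_number <- function(pd, r, dim = 0) {
  feats <- pd[pd$dimension == dim, , drop = FALSE]
  sum(feats$birth <= r & r < feats$death)
}

#' Write a persistence diagram / Betti curve to CSV
#'
#' Diagrams are written as `dimension,birth,death` with `inf` for essential
#' features; curves as `scale,H0,H1`.
#'
#' @param x A `persistence_diagram` or `betti_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tda_csv <- function(x, path) {
  df <- as.data.frame(x)
  if ("death" %in% names(df))
    df$death <- ifelse(is.finite(df$death), as.character(df$death), "inf")
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_tda_csv
#' @export
read_persistence_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = "death")))
  df$death <- ifelse(df$death == "inf", Inf, as.numeric(df$death))
  class(df) <- c("persistence_diagram", "data.frame")
  df
}
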