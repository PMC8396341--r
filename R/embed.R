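#' UMAP embedding and HDBSCAN clustering of a feature cloud
#'
#' Projects the high-dimensional activations to a low `b`-dimensional space
#' with UMAP (minimum distance 0 so dense groups may collapse, default 25
#' neighbors so each neighborhood spans more than one slide) and extracts
#' dense regions with HDBSCAN (minimum cluster size 5, minimum samples 16).
#' A separate 2-D projection is returned for display only. Label `-1` marks
#' noise points.
#'
#' Both algorithms are delegated to the reference implementations
#' (`umap-learn` and scikit-learn's HDBSCAN) through a Python subprocess;
#' only the pipeline, parameterization and seeding are owned here.
#'
#' @param cloud Numeric matrix / `feature_cloud`, one observation per row.
#' @param metric Distance in the original feature space: `"L2"`, `"L1"` or
#'   `"cosine"`.
#' @param dim Embedding dimension `b` (default 4).
#' @param neighbors UMAP neighborhood size (default 25; 15 reproduces the
#'   alternative setting used for some figures).
#' @param min_dist UMAP minimum distance (default 0).
#' @param min_cluster_size,min_samples HDBSCAN density parameters.
#' @param seed Integer seed fixing both projections.
#' @param python Python interpreter to use.
#' @return List with `labels` (integer, `-1` = noise), `coords2d` (n x 2
#'   matrix), `n_clusters` (non-noise cluster count).
#' @export
embed_and_cluster <- function(cloud, metric = c("L2", "L1", "cosine"),
                              dim = 4, neighbors = 25, min_dist = 0,
                              min_cluster_size = 5, min_samples = 16,
                              seed = 0, python = "python") {
  metric <- match.arg(metric)
  x <- unclass(as.matrix(cloud))
  assert_that(nrow(x) >= neighbors + 1,
              sprintf("need at least neighbors+1 = %d observations, got %d",
                      neighbors + 1, nrow(x)))
  py_metric <- c(L2 = "euclidean", L1 = "manhattan", cosine = "cosine")[metric]
  script <- system.file("python", "embed_cluster.py", package = "tilmap")
  assert_that(nzchar(script), "bundled python helper not found")
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  data.table::fwrite(data.table::as.data.table(x), fin, col.names = FALSE)
  status <- suppressWarnings(system2(
    python,
    c(script, "--input", fin, "--output", fout,
      "--metric", py_metric, "--dim", dim, "--neighbors", neighbors,
      "--min-dist", min_dist, "--min-cluster-size", min_cluster_size,
      "--min-samples", min_samples, "--seed", seed),
    stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status") %||% 0L
  if (code != 0)
    stop("embedding subprocess failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  res <- as.data.frame(data.table::fread(fout))
  list(labels = as.integer(res$label),
       coords2d = as.matrix(res[, c("x2d", "y2d")]),
       n_clusters = length(setdiff(unique(res$label), -1)))
}

#' Write clustering output to CSV
#'
#' @param result An [embed_and_cluster()] result.
#' @param tile_ids Identifiers for the rows.
#' @param path Output CSV (`tile_id,label,x2d,y2d`).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(result, tile_ids, path) {
  data.table::fwrite(data.frame(tile_id = tile_ids, label = result$labels,
                                x2d = result$coords2d[, 1],
                                y2d = result$coords2d[, 2]),
                     path)
  invisible(path)
}
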