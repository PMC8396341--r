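#' Read and write point annotations
#'
#' Two interchange formats are supported: a flat CSV with header
#' `tile_id,x,y` and VIA-2 compatible JSON point regions. Fractional
#' coordinates are preserved; `write` then `read` is the identity on valid
#' files.
#'
#' @param path File path; format is chosen by extension (`.csv` or
#'   `.json`) unless `format` is given.
#' @param format `"csv"` or `"via"`.
#' @return A data frame with columns `tile_id`, `x`, `y` (0-based pixel
#'   coordinates, possibly fractional).
#' @export
read_annotations <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path, ignore.case = TRUE))
    "via" else "csv"
  if (format == "csv") {
    df <- as.data.frame(data.table::fread(path, colClasses = list(
      character = "tile_id")))
    req <- c("tile_id", "x", "y")
    assert_that(all(req %in% names(df)),
                paste0(path, ": expected header tile_id,x,y"))
    # a non-numeric entry makes fread read the whole column as character
    xs <- suppressWarnings(as.numeric(df$x))
    ys <- suppressWarnings(as.numeric(df$y))
    bad <- which(!is.finite(xs) | !is.finite(ys))
    if (length(bad))
      stop(sprintf("%s: malformed coordinate on data row %d", path, bad[1]),
           call. = FALSE)
    df$x <- xs; df$y <- ys
    df[req]
  } else {
    via <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- list()
    for (entry in via) {
      tile <- sub("\\.png$", "", entry$filename %||% "")
      for (reg in entry$regions %||% list()) {
        sa <- reg$shape_attributes
        if (!identical(sa$name, "point")) next
        rows[[length(rows) + 1]] <- data.frame(
          tile_id = tile, x = as.numeric(sa$cx), y = as.numeric(sa$cy))
      }
    }
    if (!length(rows))
      return(data.frame(tile_id = character(0), x = numeric(0),
                        y = numeric(0)))
    do.call(rbind, rows)
  }
}

#' @rdname read_annotations
#' @param annotations Data frame with `tile_id`, `x`, `y`.
#' @export
write_annotations <- function(annotations, path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path, ignore.case = TRUE))
    "via" else "csv"
  req <- c("tile_id", "x", "y")
  assert_that(all(req %in% names(annotations)),
              "annotations need columns tile_id, x, y")
  if (format == "csv") {
    data.table::fwrite(annotations[req], path)
  } else {
    per_tile <- split(annotations, annotations$tile_id)
    out <- lapply(per_tile, function(df) {
      fname <- paste0(df$tile_id[1], ".png")
      list(filename = fname, size = -1,
           regions = lapply(seq_len(nrow(df)), function(i) {
             list(shape_attributes = list(name = "point",
                                          cx = df$x[i], cy = df$y[i]),
                  region_attributes = setNames(list(), character(0)))
           }),
           file_attributes = setNames(list(), character(0)))
    })
    names(out) <- vapply(out, function(e) paste0(e$filename, e$size), "")
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
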