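#' Default pipeline configuration
#'
#' One structured configuration object covers every stage; each default
#' matches the corresponding module's documented choice. The object
#' round-trips losslessly through JSON ([write_config()] /
#' [read_config()]), and its hash tags all log lines.
#'
#' @param seed Global seed.
#' @param output_dir Artifact directory for CLI runs.
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1, output_dir = "tilmap-out") {
  structure(list(
    seed = seed,
    output_dir = output_dir,
    simulate = list(n_slides = 8, tiles_per_slide = 10, width = 512,
                    height = 512, test_fraction = 0.25,
                    morphology = tile_morphology()),
    targets = list(d = 1, sigma = 4, l = 25, normalize = TRUE),
    model = list(preset = "tiny", scse = TRUE, lr = 1e-2,
                 sched_factor = 0.2, sched_patience = 10),
    train = list(epochs = 20, checkpoint_every = 6),
    detect = list(min_seed_separation = 8, min_area = 0),
    evaluate = list(threshold = 8, count_mode = "detections"),
    quantify = list(resolution = 0.5),
    tda = list(maxdim = 1, discard_fraction = 0.1, embed_dim = 4,
               neighbors = 25, min_dist = 0, min_cluster_size = 5,
               min_samples = 16, metric = "L2", tiles_per_slide = 20)
  ), class = "pipeline_config")
}

#' @rdname default_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- unclass(default_config())
  merged <- utils::modifyList(base, cfg)
  structure(merged, class = "pipeline_config")
}

#' @rdname default_config
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           null = "null")
  hash_string(as.character(json))
}
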