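# YAML serialisation of run configurations and PNG/CSV frame I/O.
# Frames travel as 8-bit grayscale PNG, one combined page per time
# point: left half BF, right half FL. Ground truth and object tables
# are RFC 4180 CSV.

config_to_list <- function(config) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$optics <- unclass(x$optics)
  x$stream <- unclass(x$stream)
  x$pulse <- unclass(x$pulse)
  x$geometry <- unclass(x$geometry)
  x$rules <- list(edges = x$rules$edges, labels = x$rules$labels,
                  require_nuclei = x$rules$require_nuclei)
  x
}

config_from_list <- function(x) {
  required <- c("optics", "stream", "population", "rules", "pulse",
                "geometry", "thresholds", "bins", "registration_offset",
                "seed")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("config validation error: missing key(s): ",
         paste(missing, collapse = ", "))
  run_config(
    optics = do.call(optics_model, x$optics),
    stream = do.call(stream_model,
                     c(x$stream,
                       list(frame_height = x$optics$frame_height))),
    population = x$population,
    rules = do.call(band_ruleset, x$rules),
    pulse = do.call(sort_pulse, x$pulse),
    geometry = do.call(channel_geometry, x$geometry),
    thresholds = x$thresholds,
    bins = x$bins,
    registration_offset = x$registration_offset,
    seed = x$seed)
}

#' Write / read a run configuration as YAML
#'
#' The round trip is lossless: `read_run_config(write_run_config(cfg))`
#' reproduces `cfg`.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  config_from_list(yaml::read_yaml(path))
}

#' Stable hash of a run configuration
#'
#' @param config A [run_config()].
#' @return Character SHA-1 digest of the canonical YAML text.
#' @export
config_hash <- function(config) {
  digest::digest(yaml::as.yaml(config_to_list(config), precision = 15),
                 algo = "sha1", serialize = FALSE)
}

#' Write / read one combined dual-view frame as 8-bit grayscale PNG
#'
#' @param frame_pair A `frame_pair` (only `bf` and `fl` are stored).
#' @param path PNG file path.
#' @return `write_frame_png` returns `path` invisibly; `read_frame_png`
#'   returns a list with integer `bf` and `fl` matrices.
#' @export
write_frame_png <- function(frame_pair, path) {
  png::writePNG(cbind(frame_pair$bf, frame_pair$fl) / 255, path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path) {
  if (!file.exists(path)) stop("cannot read frame: ", path)
  img <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop("corrupt PNG '", path, "': ",
                         conditionMessage(e)))
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (ncol(img) %% 2 != 0)
    stop("combined frame must have an even pixel width: ", path)
  w <- ncol(img) %/% 2
  to8 <- function(m) matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  list(bf = to8(img[, 1:w, drop = FALSE]),
       fl = to8(img[, (w + 1):(2 * w), drop = FALSE]))
}

#' Write a simulated stream to disk
#'
#' Lays out `frames/frame_NNNNNN.png` (combined BF|FL pages),
#' `background.png`, `ground_truth.csv` and a `manifest.json` holding
#' the seed and config hash.
#'
#' @param sim Result of [generate_stream()].
#' @param dir Output directory (created).
#' @param config The [run_config()] used.
#' @param seed The seed used.
#' @return `dir`, invisibly.
#' @export
write_stream <- function(sim, dir, config, seed = config$seed) {
  dir.create(file.path(dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  for (fp in sim$frames)
    write_frame_png(fp, file.path(dir, "frames",
                                  sprintf("frame_%06d.png",
                                          fp$frame_index)))
  bg <- background_model(config$optics)
  write_frame_png(list(bf = bg$bf_background, fl = bg$fl_background),
                  file.path(dir, "background.png"))
  utils::write.csv(sim$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- list(n_frames = length(sim$frames),
                   n_objects = nrow(sim$truth),
                   seed = seed,
                   config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_run_config(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a simulated stream directory
#'
#' @param dir Directory written by [write_stream()].
#' @return List with `frames`, `background`, `truth`, `manifest`.
#' @export
read_stream <- function(dir) {
  files <- sort(list.files(file.path(dir, "frames"),
                           pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  frames <- lapply(files, function(f) {
    fr <- read_frame_png(f)
    fr$frame_index <- as.integer(sub(".*frame_(\\d+)\\.png", "\\1", f))
    fr
  })
  bg_raw <- read_frame_png(file.path(dir, "background.png"))
  truth_path <- file.path(dir, "ground_truth.csv")
  manifest_path <- file.path(dir, "manifest.json")
  list(frames = frames,
       background = structure(list(bf_background = bg_raw$bf,
                                   fl_background = bg_raw$fl),
                              class = "background_model"),
       truth = if (file.exists(truth_path))
         utils::read.csv(truth_path) else NULL,
       manifest = if (file.exists(manifest_path))
         jsonlite::read_json(manifest_path) else NULL)
}
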