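# End-to-end pipeline: background removal -> BF binarisation -> blob
# morphometrics -> FL nucleus detection -> position matching ->
# classification. `simulate_and_analyze()` streams generated frames
# through the analysis without keeping them in memory.

#' Full run configuration with paper-anchored defaults
#'
#' Collects every tunable of the pipeline. Defaults follow the system's
#' stated constants: 300 um^2 sort trigger, 8.3 um routing threshold,
#' 40 V / 100 us pulse, FL floor 16 of 256, 20 um^2 reference nucleus
#' area, 20-um^2 area bins and 0.2 aspect-ratio bins.
#'
#' @param optics An [optics_model()].
#' @param stream A [stream_model()].
#' @param population List with `day` and `condition` selecting a
#'   [default_population()].
#' @param rules A [band_ruleset()].
#' @param pulse A [sort_pulse()].
#' @param geometry A [channel_geometry()].
#' @param thresholds Named list: `bf_k`, `fl_floor`, `min_blob_area_um2`,
#'   `min_nucleus_area_um2`, `trigger_area_um2`,
#'   `reference_nucleus_area_um2`, `min_seed_separation_um`,
#'   `match_tolerance_px`.
#' @param bins Histogram bin conventions per variable.
#' @param registration_offset FL-to-BF pixel offset `(d_row, d_col)`.
#' @param seed Integer seed recorded with the run.
#' @return A `run_config`.
#' @export
run_config <- function(optics = optics_model(),
                       stream = stream_model(frame_height =
                                               optics$frame_height),
                       population = list(day = 11L,
                                         condition = "positive"),
                       rules = band_ruleset(),
                       pulse = sort_pulse(),
                       geometry = channel_geometry(),
                       thresholds = list(bf_k = 3,
                                         fl_floor = 16,
                                         min_blob_area_um2 = 10,
                                         min_nucleus_area_um2 = 4,
                                         trigger_area_um2 = 300,
                                         reference_nucleus_area_um2 = 20,
                                         min_seed_separation_um = 6,
                                         match_tolerance_px = 2),
                       bins = list(area = list(width = 20, origin = 10),
                                   aspect_ratio = list(width = 0.2,
                                                       origin = 1),
                                   perimeter = list(width = 10,
                                                    origin = 0)),
                       registration_offset = c(0, 0),
                       seed = 1L) {
  required <- c("bf_k", "fl_floor", "min_blob_area_um2",
                "min_nucleus_area_um2", "trigger_area_um2",
                "reference_nucleus_area_um2", "min_seed_separation_um",
                "match_tolerance_px")
  missing <- setdiff(required, names(thresholds))
  if (length(missing))
    stop("missing threshold key(s): ", paste(missing, collapse = ", "))
  structure(list(optics = optics, stream = stream,
                 population = population, rules = rules, pulse = pulse,
                 geometry = geometry, thresholds = thresholds,
                 bins = bins,
                 registration_offset = registration_offset,
                 seed = as.integer(seed)),
            class = "run_config")
}

empty_records <- function() {
  data.frame(object_id = integer(0), frame = integer(0),
             area_um2 = numeric(0), perimeter_um = numeric(0),
             aspect_ratio = numeric(0), cell_count_bf = integer(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             nucleus_count = integer(0),
             nucleus_total_area_um2 = numeric(0),
             cell_count_nuc = integer(0), label = character(0))
}

#' Analyse one paired BF/FL frame
#'
#' Runs background subtraction, binarisation, blob detection and all six
#' imaging biomarkers, then classifies each object.
#'
#' @param frame_pair A `frame_pair` (or any list with `bf`/`fl` matrices
#'   and optionally `frame_index`, `registration_offset`).
#' @param background A [background_model()].
#' @param config A [run_config()].
#' @return Data frame of object records (one row per detected blob).
#' @export
analyze_frame_pair <- function(frame_pair, background,
                               config = run_config()) {
  th <- config$thresholds
  optics <- config$optics
  bf_diff <- subtract_background(frame_pair$bf, background$bf_background)
  bf_mask <- binarize_bf(bf_diff, th$bf_k)
  bs <- detect_blobs(bf_mask, optics, th$min_blob_area_um2)
  if (length(bs$blobs) == 0) return(empty_records())
  bm <- measure_blobs(bs, optics, th$min_seed_separation_um)
  fl_diff <- subtract_background(frame_pair$fl, background$fl_background)
  fl_mask <- binarize_fl(fl_diff, th$fl_floor)
  nuclei <- detect_nuclei(fl_mask, optics, th$min_nucleus_area_um2)
  off <- if (!is.null(frame_pair$registration_offset))
    frame_pair$registration_offset else config$registration_offset
  mt <- match_nuclei_to_blobs(nuclei, bs, off, th$match_tolerance_px)
  rec <- cbind(bm, mt$matches[match(bm$blob_id, mt$matches$blob_id),
                              c("nucleus_count",
                                "nucleus_total_area_um2")])
  rec$cell_count_nuc <-
    estimate_cells_from_nucleus_area(rec$nucleus_total_area_um2,
                                     th$reference_nucleus_area_um2)
  rec$label <- classify(rec$area_um2, rec$nucleus_count, config$rules)
  fi <- if (!is.null(frame_pair$frame_index)) frame_pair$frame_index
        else NA_integer_
  data.frame(object_id = rec$blob_id, frame = fi, rec[, -1],
             row.names = NULL)
}

#' Analyse a sequence of frame pairs
#'
#' @param frames List of `frame_pair`s.
#' @param background A [background_model()].
#' @param config A [run_config()].
#' @return One data frame of object records over all frames with
#'   globally unique `object_id`s; per-frame processing latency (s) is
#'   attached as attribute `"latency_s"`.
#' @export
analyze_stream <- function(frames, background, config = run_config()) {
  out <- vector("list", length(frames))
  lat <- numeric(length(frames))
  for (i in seq_along(frames)) {
    t0 <- proc.time()[["elapsed"]]
    out[[i]] <- analyze_frame_pair(frames[[i]], background, config)
    lat[i] <- proc.time()[["elapsed"]] - t0
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) res <- empty_records()
  else res$object_id <- seq_len(nrow(res))
  attr(res, "latency_s") <- lat
  res
}

# nearest-centroid match of detected records to ground truth within one
# frame; NA where nothing lies within max_dist_px
.match_truth <- function(records, truth, max_dist_px = 20) {
  if (nrow(records) == 0 || nrow(truth) == 0)
    return(rep(NA_integer_, nrow(records)))
  vapply(seq_len(nrow(records)), function(i) {
    d2 <- (truth$centroid_row - records$centroid_row[i])^2 +
      (truth$centroid_col - records$centroid_col[i])^2
    j <- which.min(d2)
    if (d2[j] <= max_dist_px^2) j else NA_integer_
  }, 0L)
}

#' Simulate a frame stream and analyse it on the fly
#'
#' Generates frames (as [generate_stream()] would) and pushes each
#' through [analyze_frame_pair()] immediately, so arbitrarily long
#' streams fit in memory. Detected records are matched to ground truth
#' by nearest centroid.
#'
#' @param config A [run_config()] (population, optics, stream and all
#'   thresholds are taken from it).
#' @param n_objects Stop after this many ground-truth objects have been
#'   imaged (the last frame is completed).
#' @param n_frames Alternatively, a fixed number of frames.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param progress Print a dot every 1000 frames.
#' @return List with `records` (detected objects, plus `true_label`,
#'   `true_area`, `true_cell_count`, `true_nucleus_count` columns where
#'   matched) and `truth` (all generated objects).
#' @export
simulate_and_analyze <- function(config = run_config(), n_objects = NULL,
                                 n_frames = NULL, seed = config$seed,
                                 progress = FALSE) {
  stopifnot(xor(is.null(n_objects), is.null(n_frames)))
  set.seed(seed)
  optics <- config$optics
  stream <- config$stream
  pop <- default_population(config$population$day,
                            config$population$condition)
  bg <- background_model(optics)
  ps <- optics$pixel_size
  spacing_px <- stream$min_spacing_um / ps
  margin_px <- ceiling(spacing_px * 0.7)
  capacity <- max(1L, floor((optics$frame_width - 2 * margin_px) /
                              spacing_px) + 1L)
  queue <- 0L
  produced <- 0L
  f <- 0L
  recs <- list()
  truths <- list()
  repeat {
    f <- f + 1L
    if (!is.null(n_frames) && f > n_frames) break
    if (!is.null(n_objects) && produced >= n_objects && queue == 0L) break
    queue <- queue + rpois(1, stream$arrival_rate)
    if (!is.null(n_objects))
      queue <- min(queue, n_objects - produced)
    k <- min(queue, capacity)
    queue <- queue - k
    objs <- if (k > 0) replicate(k, sample_object(pop, optics),
                                 simplify = FALSE) else list()
    fp <- render_frame_pair(objs, optics, stream, frame_index = f,
                            registration_offset =
                              config$registration_offset)
    produced <- produced + k
    rec <- analyze_frame_pair(fp, bg, config)
    if (nrow(rec) > 0) {
      j <- .match_truth(rec, fp$truth,
                        max_dist_px = spacing_px / 2)
      rec$true_label <- fp$truth$label[j]
      rec$true_area <- fp$truth$true_area[j]
      rec$true_cell_count <- fp$truth$true_cell_count[j]
      rec$true_nucleus_count <- fp$truth$true_nucleus_count[j]
      recs[[length(recs) + 1L]] <- rec
    }
    if (nrow(fp$truth) > 0)
      truths[[length(truths) + 1L]] <- cbind(frame = f, fp$truth)
    if (progress && f %% 1000L == 0L) cat(".")
  }
  if (progress) cat("\n")
  records <- if (length(recs)) do.call(rbind, recs) else {
    er <- empty_records()
    er$true_label <- character(0); er$true_area <- numeric(0)
    er$true_cell_count <- integer(0); er$true_nucleus_count <- integer(0)
    er
  }
  if (nrow(records) > 0) records$object_id <- seq_len(nrow(records))
  truth <- if (length(truths)) do.call(rbind, truths) else
    cbind(frame = integer(0), empty_truth())
  list(records = records, truth = truth)
}
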