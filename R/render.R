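# Rendering of paired BF/FL frames. The combined acquisition places the
# bright-field view on the left half of the sensor and the fluorescence
# view on the right half; both views share pixel coordinates, so a
# nucleus appears at the same (row, col) in the FL view as its parent
# cell in the BF view (up to a configurable registration offset).

clip8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# draw object column positions with minimum spacing inside [margin, W-margin];
# returns NULL if k objects cannot fit
.place_columns <- function(k, width_px, spacing_px, margin_px) {
  if (k == 0) return(numeric(0))
  avail <- (width_px - 2 * margin_px) - (k - 1) * spacing_px
  if (avail < 0) return(NULL)
  base <- sort(runif(k, 0, avail))
  margin_px + base + (seq_len(k) - 1) * spacing_px
}

#' Render one paired BF/FL frame from ground-truth objects
#'
#' Objects are placed on the focused lane (row `lane_center` plus
#' Gaussian jitter) at random columns separated by at least
#' `min_spacing_um`; the BF view shows each object as an intensity drop
#' below the background, the FL view shows only the nuclei, then
#' Gaussian sensor noise is added and intensities are clipped to 0--255.
#'
#' @param objects List of `gt_object`s (from [sample_object()]).
#' @param optics An [optics_model()].
#' @param stream A [stream_model()].
#' @param frame_index Integer frame number (metadata).
#' @param registration_offset `(d_row, d_col)` pixel shift applied to the
#'   FL channel relative to BF (default `c(0, 0)`).
#' @return A `frame_pair`: integer matrices `bf` and `fl`
#'   (`frame_height x frame_width` each), a `truth` data frame (one row
#'   per object) and a `labels` integer matrix of ground-truth masks.
#' @export
render_frame_pair <- function(objects, optics, stream, frame_index = 1L,
                              registration_offset = c(0, 0)) {
  h <- optics$frame_height
  w <- optics$frame_width
  ps <- optics$pixel_size
  k <- length(objects)
  spacing_px <- stream$min_spacing_um / ps
  margin_px <- ceiling(spacing_px * 0.7)
  cols <- .place_columns(k, w, spacing_px, margin_px)
  if (is.null(cols))
    stop("placement error: ", k, " objects do not fit in one frame at ",
         stream$min_spacing_um, " um spacing")
  rows <- stream$lane_center +
    rnorm(k, 0, stream$lane_jitter_sd / ps)

  bf <- matrix(optics$bf_background_level, h, w)
  fl <- matrix(optics$fl_background_level, h, w)
  labels <- matrix(0L, h, w)
  truth <- vector("list", k)
  for (i in seq_len(k)) {
    ob <- objects[[i]]
    r0 <- round(rows[i]) - ob$origin[1]
    c0 <- round(cols[i]) - ob$origin[2]
    idx <- which(ob$mask, arr.ind = TRUE)
    rr <- idx[, 1] + r0
    cc <- idx[, 2] + c0
    if (any(rr < 1 | rr > h | cc < 1 | cc > w))
      stop("placement error: object ", i, " extends outside the view")
    bf[cbind(rr, cc)] <- optics$bf_background_level - optics$bf_contrast
    labels[cbind(rr, cc)] <- i
    if (any(ob$nuc_mask)) {
      nidx <- which(ob$nuc_mask, arr.ind = TRUE)
      nr <- nidx[, 1] + r0 + registration_offset[1]
      nc <- nidx[, 2] + c0 + registration_offset[2]
      keep <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
      fl[cbind(nr[keep], nc[keep])] <-
        optics$fl_background_level + optics$fl_nucleus_peak
    }
    truth[[i]] <- data.frame(
      object_id = i, label = ob$label, true_area = ob$true_area,
      true_cell_count = ob$true_cell_count,
      true_nucleus_count = ob$true_nucleus_count,
      true_nucleus_total_area = ob$true_nucleus_total_area,
      centroid_row = mean(rr), centroid_col = mean(cc))
  }
  if (optics$noise_sd > 0) {
    bf <- bf + rnorm(h * w, 0, optics$noise_sd)
    fl <- fl + rnorm(h * w, 0, optics$noise_sd)
  }
  structure(list(bf = matrix(as.integer(round(clip8(bf))), h, w),
                 fl = matrix(as.integer(round(clip8(fl))), h, w),
                 frame_index = as.integer(frame_index),
                 timestamp = frame_index / stream$frame_rate,
                 registration_offset = registration_offset,
                 truth = if (k > 0) do.call(rbind, truth) else
                   empty_truth(),
                 labels = labels),
            class = "frame_pair")
}

empty_truth <- function() {
  data.frame(object_id = integer(0), label = character(0),
             true_area = numeric(0), true_cell_count = integer(0),
             true_nucleus_count = integer(0),
             true_nucleus_total_area = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0))
}

#' Generate a reproducible synthetic frame stream with ground truth
#'
#' Per-frame object counts are Poisson(`arrival_rate`); objects that do
#' not fit a frame at the configured spacing queue up for the next frame
#' (hydrodynamic back-pressure), so total counts are conserved.
#'
#' @param pop A [population_model()].
#' @param optics An [optics_model()].
#' @param stream A [stream_model()].
#' @param n_frames Number of frames (>= 1).
#' @param seed Optional integer seed; fixed seed gives bit-identical
#'   output.
#' @param registration_offset FL-vs-BF pixel offset, passed through.
#' @return List with `frames` (list of `frame_pair`) and `truth` (one
#'   data frame over all frames, with a `frame` column).
#' @export
generate_stream <- function(pop, optics = optics_model(),
                            stream = stream_model(frame_height =
                                                    optics$frame_height),
                            n_frames, seed = NULL,
                            registration_offset = c(0, 0)) {
  stopifnot(n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  ps <- optics$pixel_size
  spacing_px <- stream$min_spacing_um / ps
  margin_px <- ceiling(spacing_px * 0.7)
  capacity <- max(1L, floor((optics$frame_width - 2 * margin_px) /
                              spacing_px) + 1L)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  queue <- 0L
  next_id <- 1L
  for (f in seq_len(n_frames)) {
    queue <- queue + rpois(1, stream$arrival_rate)
    k <- min(queue, capacity)
    queue <- queue - k
    objs <- if (k > 0) replicate(k, sample_object(pop, optics),
                                 simplify = FALSE) else list()
    fp <- render_frame_pair(objs, optics, stream, frame_index = f,
                            registration_offset = registration_offset)
    if (nrow(fp$truth) > 0) {
      fp$truth$object_id <- seq(next_id, length.out = nrow(fp$truth))
      fp$labels[fp$labels > 0] <- fp$labels[fp$labels > 0] + (next_id - 1L)
      next_id <- next_id + nrow(fp$truth)
      truth[[f]] <- cbind(frame = f, fp$truth)
    }
    frames[[f]] <- fp
  }
  truth <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
  if (is.null(truth)) truth <- cbind(frame = integer(0), empty_truth())
  list(frames = frames, truth = truth)
}
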