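# Fluorescence channel processing and BF-FL position matching. Both
# views come from the same sensor, so nucleus coordinates map onto the
# BF view directly (plus a configurable registration offset); a nucleus
# belongs to the blob whose (tolerance-dilated) mask contains its
# centroid.

#' Binarise a background-subtracted FL grid
#'
#' A pixel is a nucleus candidate iff its background-subtracted value
#' strictly exceeds `floor`. The default floor of 16 (the lower 4 bits
#' of the 8-bit range) reflects that recorded nucleus intensities sit
#' well above the bottom 16 of 256 grey steps even though the FL channel
#' is an order of magnitude dimmer than BF.
#'
#' @param fl_diff_grid Nonnegative matrix from [subtract_background()].
#' @param floor 8-bit threshold (default 16).
#' @return Logical mask.
#' @export
binarize_fl <- function(fl_diff_grid, floor = 16) {
  fl_diff_grid > floor
}

#' Detect nuclei in a binary FL mask
#'
#' 8-connected components; components smaller than `min_area_um2`
#' (default 4 um^2) are discarded as noise. Touching nuclei merge into
#' one component (undercount risk, mirrored by the estimator based on
#' total nucleus area).
#'
#' @param fl_mask Logical matrix.
#' @param optics An [optics_model()].
#' @param min_area_um2 Minimum nucleus area kept, um^2.
#' @return Data frame: `nucleus_id`, `area_um2`, `centroid_row`,
#'   `centroid_col` (FL coordinates).
#' @export
detect_nuclei <- function(fl_mask, optics, min_area_um2 = 4) {
  lab <- cc_label(fl_mask, 8L)
  n <- max(lab)
  if (n == 0)
    return(data.frame(nucleus_id = integer(0), area_um2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  idx <- which(lab > 0)
  ids <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  sizes <- tabulate(ids, n)
  cr <- vapply(split(rows, ids), mean, 0)
  cc <- vapply(split(cols, ids), mean, 0)
  keep <- sizes * optics$pixel_size^2 >= min_area_um2
  data.frame(nucleus_id = seq_len(sum(keep)),
             area_um2 = sizes[keep] * optics$pixel_size^2,
             centroid_row = unname(cr[keep]),
             centroid_col = unname(cc[keep]))
}

#' Match detected nuclei to BF blobs
#'
#' Each nucleus centroid, translated by the registration offset, is
#' assigned to the blob whose mask (dilated by `tolerance_px` in the
#' Chebyshev sense) contains it; ambiguous centroids go to the nearest
#' blob pixel. Every blob receives a result (possibly zero nuclei);
#' unassigned nuclei are flagged unmatched.
#'
#' @param nuclei Data frame from [detect_nuclei()].
#' @param blob_set A `blob_set` from [detect_blobs()].
#' @param registration_offset `(d_row, d_col)` pixels mapping FL onto BF
#'   coordinates.
#' @param tolerance_px Dilation radius absorbing segmentation edge noise
#'   (default 2).
#' @return List with `matches` (data frame `blob_id`, `nucleus_count`,
#'   `nucleus_total_area_um2`), `nucleus_parent` (integer vector, NA for
#'   unmatched) and `unmatched` (nucleus ids).
#' @export
match_nuclei_to_blobs <- function(nuclei, blob_set,
                                  registration_offset = c(0, 0),
                                  tolerance_px = 2) {
  lab <- blob_set$labels
  nb <- length(blob_set$blobs)
  parent <- rep(NA_integer_, nrow(nuclei))
  if (nrow(nuclei) > 0 && nb > 0) {
    h <- nrow(lab); w <- ncol(lab)
    for (i in seq_len(nrow(nuclei))) {
      r <- round(nuclei$centroid_row[i] - registration_offset[1])
      c <- round(nuclei$centroid_col[i] - registration_offset[2])
      rr <- max(1, r - tolerance_px):min(h, r + tolerance_px)
      cc <- max(1, c - tolerance_px):min(w, c + tolerance_px)
      win <- lab[rr, cc, drop = FALSE]
      hit <- which(win > 0, arr.ind = TRUE)
      if (nrow(hit) == 0) next
      d2 <- (rr[hit[, 1]] - r)^2 + (cc[hit[, 2]] - c)^2
      parent[i] <- win[hit[which.min(d2), , drop = FALSE]]
    }
  }
  counts <- tabulate(parent[!is.na(parent)], nb)
  tot <- rep(0, nb)
  if (any(!is.na(parent))) {
    agg <- tapply(nuclei$area_um2[!is.na(parent)],
                  parent[!is.na(parent)], sum)
    tot[as.integer(names(agg))] <- agg
  }
  list(matches = data.frame(blob_id = seq_len(nb),
                            nucleus_count = counts,
                            nucleus_total_area_um2 = tot),
       nucleus_parent = parent,
       unmatched = nuclei$nucleus_id[is.na(parent)])
}

#' Estimate cell count from total nucleus area
#'
#' Divides the total stained area of an object by a typical
#' single-nucleus area (default 20 um^2, the first peak of the nucleus
#' area distribution) and rounds to the nearest integer, never below 1
#' for a positive total. Multinucleate cells carry an overestimation
#' risk.
#'
#' @param nucleus_total_area_um2 Total nucleus area of an object, um^2
#'   (vectorised).
#' @param reference_area_um2 Typical single-nucleus area, um^2 (> 0).
#' @return Integer estimated cell count (0 for zero total area).
#' @export
estimate_cells_from_nucleus_area <- function(nucleus_total_area_um2,
                                             reference_area_um2 = 20) {
  if (reference_area_um2 <= 0) stop("reference_area_um2 must be > 0")
  if (any(nucleus_total_area_um2 < 0))
    stop("nucleus_total_area_um2 must be nonnegative")
  est <- pmax(1L, as.integer(round(nucleus_total_area_um2 /
                                     reference_area_um2)))
  est[nucleus_total_area_um2 == 0] <- 0L
  est
}
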