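# Bright-field channel processing: background removal, mean-based
# binarisation, connected-component blob detection, and the four BF
# imaging biomarkers (area, Crofton perimeter, aspect ratio from the
# minimum-area rotated rectangle, and watershed cell count).

#' Absolute background subtraction
#'
#' Removes a pre-recorded background image from a frame channel. The
#' absolute deviation is used so that both darker (BF absorption) and
#' brighter (FL emission) object pixels register.
#'
#' @param frame_channel,background_channel Numeric matrices of identical
#'   dimensions (8-bit intensities).
#' @return Nonnegative numeric matrix `|frame - background|`.
#' @export
subtract_background <- function(frame_channel, background_channel) {
  if (!all(dim(frame_channel) == dim(background_channel)))
    stop("frame and background dimensions differ")
  abs(frame_channel - background_channel)
}

#' Binarise a background-subtracted BF grid
#'
#' Thresholds at a multiple of the grid's mean intensity: a pixel is
#' foreground iff its value strictly exceeds `k * mean(diff_grid)`. An
#' all-zero grid yields an empty mask.
#'
#' @param diff_grid Nonnegative matrix from [subtract_background()].
#' @param k Threshold multiplier (default 3).
#' @return Logical mask.
#' @export
binarize_bf <- function(diff_grid, k = 3) {
  if (any(diff_grid < 0)) stop("diff_grid must be nonnegative")
  diff_grid > k * mean(diff_grid)
}

#' Detect blobs in a binary mask
#'
#' Labels 8-connected components, fills interior holes (BF cell
#' interiors can be bright), and discards components smaller than
#' `min_area_um2` (default 10 um^2, the lower edge of the area
#' histograms).
#'
#' @param mask Logical matrix.
#' @param optics An [optics_model()] (pixel size).
#' @param min_area_um2 Minimum blob area kept, um^2.
#' @param fill_holes Fill interior holes before measuring (default TRUE).
#' @return A `blob_set`: list with `labels` (integer matrix, relabelled
#'   1..n) and `blobs`, a list of blob records each holding `id`,
#'   `pixels` (n x 2 row/col matrix), `centroid` and `bbox`.
#' @export
detect_blobs <- function(mask, optics, min_area_um2 = 10,
                         fill_holes = TRUE) {
  stopifnot(is.logical(mask))
  if (fill_holes) mask <- fill_holes_cpp(mask)
  lab <- cc_label(mask, 8L)
  n <- max(lab)
  blobs <- list()
  out_lab <- matrix(0L, nrow(lab), ncol(lab))
  min_px <- min_area_um2 / optics$pixel_size^2
  if (n > 0) {
    idx <- which(lab > 0)
    ids <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    ord <- order(ids)
    ids <- ids[ord]; rows <- rows[ord]; cols <- cols[ord]
    sizes <- tabulate(ids, n)
    keep <- which(sizes >= min_px)
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    new_id <- 0L
    for (b in keep) {
      new_id <- new_id + 1L
      sel <- starts[b]:ends[b]
      px <- cbind(row = rows[sel], col = cols[sel])
      out_lab[cbind(px[, 1], px[, 2])] <- new_id
      blobs[[new_id]] <- list(
        id = new_id, pixels = px,
        centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
        bbox = c(rmin = min(px[, 1]), rmax = max(px[, 1]),
                 cmin = min(px[, 2]), cmax = max(px[, 2])))
    }
  }
  structure(list(labels = out_lab, blobs = blobs), class = "blob_set")
}

# local padded logical mask of one blob, with 1-pixel background border
.blob_local_mask <- function(blob) {
  bb <- blob$bbox
  m <- matrix(FALSE, bb["rmax"] - bb["rmin"] + 3L,
              bb["cmax"] - bb["cmin"] + 3L)
  m[cbind(blob$pixels[, 1] - bb["rmin"] + 2L,
          blob$pixels[, 2] - bb["cmin"] + 2L)] <- TRUE
  m
}

#' Blob cross-sectional area
#'
#' @param blob One blob record from [detect_blobs()].
#' @param optics An [optics_model()].
#' @return Area in um^2 (pixel count times pixel area).
#' @export
measure_area <- function(blob, optics) {
  if (is.null(blob$pixels) || nrow(blob$pixels) == 0)
    stop("empty blob mask")
  nrow(blob$pixels) * optics$pixel_size^2
}

# Cauchy-Crofton boundary length from intercept counts in 4 directions
# (0, 45, 90, 135 degrees); diagonal sampling lines are 1/sqrt(2) px
# apart. Unbiased for smooth convex shapes, ~5% low for squares.
crofton_perimeter <- function(mask, pixel_size = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(FALSE, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- mask
  th <- sum(m[, -1] != m[, -ncol(m)])
  tv <- sum(m[-1, ] != m[-nrow(m), ])
  td1 <- sum(m[-1, -1] != m[-nrow(m), -ncol(m)])
  td2 <- sum(m[-1, -ncol(m)] != m[-nrow(m), -1])
  (pi / 8) * (th + tv + (td1 + td2) / sqrt(2)) * pixel_size
}

#' Blob perimeter (Crofton estimate)
#'
#' Boundary length estimated by the 4-direction Cauchy--Crofton formula,
#' which is calibrated for smooth contours (a naive boundary-pixel count
#' overestimates them).
#'
#' @inheritParams measure_area
#' @return Perimeter in um.
#' @export
measure_perimeter <- function(blob, optics) {
  crofton_perimeter(.blob_local_mask(blob), optics$pixel_size)
}

# minimum-area rotated rectangle over the pixel-square corners of a
# point set; returns c(long, short) side lengths in px
min_area_rect <- function(pixels) {
  pts <- rbind(cbind(pixels[, 1] - 0.5, pixels[, 2] - 0.5),
               cbind(pixels[, 1] - 0.5, pixels[, 2] + 0.5),
               cbind(pixels[, 1] + 0.5, pixels[, 2] - 0.5),
               cbind(pixels[, 1] + 0.5, pixels[, 2] + 0.5))
  h <- chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh == 1) return(c(1, 1))
  edges <- hp[c(2:nh, 1), ] - hp
  ang <- unique(round(atan2(edges[, 1], edges[, 2]) %% (pi / 2), 10))
  best <- c(Inf, Inf)
  for (a in ang) {
    ca <- cos(a); sa <- sin(a)
    x <- hp[, 2] * ca + hp[, 1] * sa
    y <- -hp[, 2] * sa + hp[, 1] * ca
    wd <- diff(range(x)); ht <- diff(range(y))
    if (wd * ht < best[1] * best[2]) best <- c(wd, ht)
  }
  c(max(best), min(best))
}

#' Blob aspect ratio
#'
#' Ratio of the longer to the shorter side of the minimum-area rotated
#' bounding rectangle; >= 1 by construction, ~1 for round objects.
#'
#' @param blob One blob record from [detect_blobs()].
#' @return Dimensionless aspect ratio.
#' @export
measure_aspect_ratio <- function(blob) {
  s <- min_area_rect(blob$pixels)
  s[1] / s[2]
}

#' Estimate the number of cells in a blob from its BF silhouette
#'
#' Seeds are local maxima of the Euclidean distance transform, thinned so
#' that kept seeds are at least `min_seed_separation_um` apart; a seeded
#' watershed then partitions the blob and segments smaller than the
#' 10-um^2 floor are dropped. Known to be fooled by debris attached to
#' cells -- by design, nucleus counting (FL) is the robust counterpart.
#'
#' @inheritParams measure_area
#' @param min_seed_separation_um Minimum distance between watershed
#'   seeds, um (default 6).
#' @return Integer cell count, always >= 1.
#' @export
estimate_cell_count_bf <- function(blob, optics,
                                   min_seed_separation_um = 6) {
  m <- .blob_local_mask(blob)
  dt <- edt_sq_cpp(m)
  ps <- optics$pixel_size
  cand <- which(m & .is_local_max(dt), arr.ind = TRUE)
  if (nrow(cand) == 0) return(1L)
  vals <- dt[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  min_sep_px <- min_seed_separation_um / ps
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0 ||
        all((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2 >= min_sep_px^2))
      kept <- rbind(kept, p)
  }
  if (nrow(kept) <= 1) return(1L)
  seeds <- matrix(0L, nrow(m), ncol(m))
  seeds[kept] <- seq_len(nrow(kept))
  seg <- watershed_seeded_cpp(dt, seeds, m)
  sizes <- tabulate(seg[seg > 0], nrow(kept))
  max(1L, sum(sizes * ps^2 >= 10))
}

# 8-neighbourhood local maxima (>= all neighbours), borders padded -Inf
.is_local_max <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- x
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (x >= p[2:(nr + 1L) + dr, 2:(nc + 1L) + dc])
  }
  res
}

#' Measure all BF biomarkers for every blob in a mask
#'
#' @param blob_set Result of [detect_blobs()].
#' @param optics An [optics_model()].
#' @param min_seed_separation_um Passed to [estimate_cell_count_bf()].
#' @return Data frame with one row per blob: `blob_id`, `area_um2`,
#'   `perimeter_um`, `aspect_ratio`, `cell_count_bf`, `centroid_row`,
#'   `centroid_col`.
#' @export
measure_blobs <- function(blob_set, optics, min_seed_separation_um = 6) {
  bl <- blob_set$blobs
  if (length(bl) == 0)
    return(data.frame(blob_id = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), aspect_ratio = numeric(0),
                      cell_count_bf = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0)))
  do.call(rbind, lapply(bl, function(b) data.frame(
    blob_id = b$id,
    area_um2 = measure_area(b, optics),
    perimeter_um = measure_perimeter(b, optics),
    aspect_ratio = measure_aspect_ratio(b),
    cell_count_bf = estimate_cell_count_bf(b, optics,
                                           min_seed_separation_um),
    centroid_row = b$centroid["row"],
    centroid_col = b$centroid["col"], row.names = NULL)))
}
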