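# Population mixtures and single-object sampling for the synthetic
# frame generator. Objects are unions of disks (cells); stained nuclei
# are smaller disks fully contained in their parent cell. Debris classes
# carry no nuclei at all, which is exactly what makes them debris
# downstream.

#' One mixture component of a synthetic blood population
#'
#' @param label Class label: one of `"rbc_debris"`, `"debris_agg"`,
#'   `"wbc"`, `"large_single"`, `"cluster"`.
#' @param weight Nonnegative mixture weight.
#' @param area_median,area_log_sd Lognormal parameters (median in um^2,
#'   sd on the log scale) of the object area -- for `"cluster"` these
#'   describe the *per-cell* area, the cluster area being the emergent
#'   disk-union area.
#' @param area_range Truncation interval `[lo, hi)` in um^2 for the area
#'   draw; support must stay within (0, 1000].
#' @param cell_counts,cell_count_probs Support and probabilities of the
#'   number of cells (1 for singles, 0 cells still render as particles
#'   for debris; debris subunit counts are shape subunits, not cells).
#' @param nuclei_per_cell_probs Probabilities for 1, 2, ... nuclei in each
#'   cell; must be `NULL` (no nuclei) for debris classes.
#' @param nucleus_area_mean,nucleus_area_sd Normal parameters of single
#'   nucleus area, um^2 (truncated at 8 um^2 from below).
#' @param spacing_factor Centre spacing between touching disks as a
#'   multiple of the mean disk radius (< 2 means overlap).
#' @return A `pop_component` list.
#' @export
pop_component <- function(label, weight,
                          area_median, area_log_sd,
                          area_range = c(10, 1000),
                          cell_counts = 1L, cell_count_probs = 1,
                          nuclei_per_cell_probs = NULL,
                          nucleus_area_mean = 20, nucleus_area_sd = 3,
                          spacing_factor = 1.2) {
  stopifnot(weight >= 0, area_median > 0, area_log_sd >= 0,
            length(area_range) == 2, area_range[1] > 0,
            area_range[2] <= 1000, area_range[1] < area_range[2],
            length(cell_counts) == length(cell_count_probs),
            all(cell_count_probs >= 0), sum(cell_count_probs) > 0)
  nucleated <- !is.null(nuclei_per_cell_probs)
  if (label %in% c("rbc_debris", "debris_agg") && nucleated)
    stop("debris components must have no nuclei")
  structure(list(label = label, weight = weight,
                 area_median = area_median, area_log_sd = area_log_sd,
                 area_range = area_range,
                 cell_counts = as.integer(cell_counts),
                 cell_count_probs = cell_count_probs / sum(cell_count_probs),
                 nuclei_per_cell_probs = nuclei_per_cell_probs,
                 nucleus_area_mean = nucleus_area_mean,
                 nucleus_area_sd = nucleus_area_sd,
                 spacing_factor = spacing_factor),
            class = "pop_component")
}

#' Synthetic blood population model
#'
#' @param components List of [pop_component()] objects; weights must sum
#'   to 1 (within 1e-8).
#' @param day Study-day tag (2, 4, 7, 9 or 11).
#' @return A `population_model` object.
#' @export
population_model <- function(components, day = 11L) {
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "pop_component")))
  w <- vapply(components, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("component weights must sum to 1")
  names(components) <- vapply(components, `[[`, "", "label")
  structure(list(components = components, day = as.integer(day)),
            class = "population_model")
}

# day-course weights of the tumour-specific components; qualitative ramp:
# clusters emerge around day 7 and roughly double by day 11, large single
# cells rise sharply at days 9-11.
.day_weights <- function(day) {
  days <- c(2, 4, 7, 9, 11)
  if (!day %in% days) stop("day must be one of 2, 4, 7, 9, 11")
  i <- match(day, days)
  list(large_single = c(0.002, 0.008, 0.020, 0.030, 0.040)[i],
       cluster      = c(0.002, 0.006, 0.010, 0.015, 0.020)[i])
}

#' Default synthetic blood populations
#'
#' Calibrated fixtures, not reproductions of any measured blood: a control
#' population (red-blood-cell debris, single leukocytes and nucleus-free
#' debris aggregates) and a tumour-positive population that adds large
#' single cells in the 90--130 um^2 band and 2--6-cell clusters at
#' >= 150 um^2, with weights ramping over study days 2--11.
#'
#' @param day Study day (2, 4, 7, 9 or 11).
#' @param condition `"positive"` or `"control"`.
#' @return A [population_model()].
#' @export
default_population <- function(day = 11L, condition = c("positive", "control")) {
  condition <- match.arg(condition)
  base_rbc <- 0.45
  base_wbc <- 0.50
  base_agg <- 0.05
  comps <- list(
    rbc = pop_component("rbc_debris", base_rbc,
                        area_median = 20, area_log_sd = 0.25,
                        area_range = c(10, 30)),
    wbc = pop_component("wbc", base_wbc,
                        area_median = 60, area_log_sd = 0.10,
                        area_range = c(50, 70),
                        nuclei_per_cell_probs = 1,
                        nucleus_area_mean = 20, nucleus_area_sd = 3),
    agg = pop_component("debris_agg", base_agg,
                        area_median = 60, area_log_sd = 0.60,
                        area_range = c(10, 900),
                        cell_counts = 2:3, cell_count_probs = c(0.6, 0.4),
                        spacing_factor = 1.1))
  if (condition == "positive") {
    dw <- .day_weights(day)
    extra <- dw$large_single + dw$cluster
    scale <- 1 - extra
    comps$rbc$weight <- base_rbc * scale
    comps$wbc$weight <- base_wbc * scale
    comps$agg$weight <- base_agg * scale
    comps$large <- pop_component("large_single", dw$large_single,
                                 area_median = 110, area_log_sd = 0.08,
                                 area_range = c(90, 130),
                                 nuclei_per_cell_probs = c(0.9, 0.1),
                                 nucleus_area_mean = 30,
                                 nucleus_area_sd = 5)
    comps$cluster <- pop_component("cluster", dw$cluster,
                                   area_median = 100, area_log_sd = 0.15,
                                   area_range = c(88, 250),
                                   cell_counts = 2:6,
                                   cell_count_probs =
                                     c(0.40, 0.25, 0.18, 0.10, 0.07),
                                   nuclei_per_cell_probs = c(0.95, 0.05),
                                   nucleus_area_mean = 20,
                                   nucleus_area_sd = 3)
  }
  population_model(unname(comps), day = day)
}

# truncated lognormal draw by inverse-cdf (exact, no rejection loop)
.rlnorm_trunc <- function(n, median, log_sd, lo, hi) {
  if (log_sd == 0) return(rep(pmin(pmax(median, lo), hi), n))
  mu <- log(median)
  plo <- stats::plnorm(lo, mu, log_sd)
  phi <- stats::plnorm(hi, mu, log_sd)
  stats::qlnorm(plo + runif(n) * (phi - plo), mu, log_sd)
}

# truncated-below normal draw
.rnorm_trunc <- function(n, mean, sd, lo) {
  if (sd == 0) return(rep(max(mean, lo), n))
  p <- stats::pnorm(lo, mean, sd)
  stats::qnorm(p + runif(n) * (1 - p), mean, sd)
}

# relative (um) centre layouts for n compactly packed unit-spacing disks
.pack_layout <- function(n) {
  switch(as.character(n),
         "1" = cbind(0, 0),
         "2" = cbind(c(0, 0), c(-0.5, 0.5)),
         "3" = cbind(c(-0.289, -0.289, 0.577), c(-0.5, 0.5, 0)),
         "4" = cbind(c(-0.5, -0.5, 0.5, 0.5), c(-0.5, 0.5, -0.5, 0.5)),
         "5" = cbind(c(0, -0.951, -0.588, 0.588, 0.951) * 0.851,
                     c(1, 0.309, -0.809, -0.809, 0.309) * 0.851),
         "6" = cbind(c(0, 0.866, 0.866, 0, -0.866, -0.866),
                     c(1, 0.5, -0.5, -1, -0.5, 0.5)),
         stop("unsupported subunit count: ", n))
}

# rotate 2-column (row, col) um offsets by a random angle
.rotate <- function(xy, theta) {
  cbind(xy[, 1] * cos(theta) - xy[, 2] * sin(theta),
        xy[, 1] * sin(theta) + xy[, 2] * cos(theta))
}

# Rasterise a union of disks onto a local pixel grid centred on the
# object. Pixel (i, j) is foreground when its centre lies inside any
# disk. Returns the logical mask plus the (row, col) index of the grid
# origin (object centre).
rasterize_disks <- function(centers_um, radii_um, pixel_size) {
  ext <- max(sqrt(rowSums(centers_um^2)) + radii_um) / pixel_size
  half <- ceiling(ext) + 1L
  side <- 2L * half + 1L
  mask <- matrix(FALSE, side, side)
  for (k in seq_along(radii_um)) {
    cr <- half + 1 + centers_um[k, 1] / pixel_size
    cc <- half + 1 + centers_um[k, 2] / pixel_size
    rpx <- radii_um[k] / pixel_size
    rows <- max(1L, floor(cr - rpx)):min(side, ceiling(cr + rpx))
    cols <- max(1L, floor(cc - rpx)):min(side, ceiling(cc + rpx))
    dd <- outer((rows - cr)^2, (cols - cc)^2, `+`)
    mask[rows, cols] <- mask[rows, cols] | (dd <= rpx^2)
  }
  list(mask = mask, origin = c(half + 1L, half + 1L))
}

#' Draw one ground-truth object from a population mixture
#'
#' Samples a component by weight, draws its geometry (cells as
#' overlapping disks, nuclei as smaller disks strictly inside their
#' cell), and rasterises it on the pixel grid of `optics`. The returned
#' ground truth carries the exact rasterised areas.
#'
#' Uses R's global random number stream; call `set.seed()` for
#' reproducibility.
#'
#' @param pop A [population_model()].
#' @param optics An [optics_model()] (supplies the pixel grid).
#' @return A `gt_object`: label, true areas (um^2), cell/nucleus counts,
#'   disk parameters and local rasterised masks for both channels.
#' @export
sample_object <- function(pop, optics = optics_model()) {
  stopifnot(inherits(pop, "population_model"))
  w <- vapply(pop$components, `[[`, 0, "weight")
  comp <- pop$components[[sample.int(length(w), 1, prob = w)]]
  ps <- optics$pixel_size

  if (comp$label %in% c("rbc_debris", "wbc", "large_single")) {
    n_sub <- 1L
    areas <- .rlnorm_trunc(1, comp$area_median, comp$area_log_sd,
                           comp$area_range[1], comp$area_range[2])
  } else {
    n_sub <- comp$cell_counts[sample.int(length(comp$cell_counts), 1,
                                         prob = comp$cell_count_probs)]
    areas <- .rlnorm_trunc(n_sub, comp$area_median, comp$area_log_sd,
                           comp$area_range[1], comp$area_range[2])
  }
  radii <- sqrt(areas / pi)
  spacing <- comp$spacing_factor * mean(radii)
  centers <- .rotate(.pack_layout(n_sub) * spacing, runif(1, 0, 2 * pi))
  centers <- sweep(centers, 2, colMeans(centers))

  nucleated <- !is.null(comp$nuclei_per_cell_probs)
  n_cells <- if (nucleated) n_sub else 0L
  nuc_centers <- NULL
  nuc_radii <- numeric(0)
  if (nucleated) {
    for (k in seq_len(n_sub)) {
      n_nuc_k <- sample.int(length(comp$nuclei_per_cell_probs), 1,
                            prob = comp$nuclei_per_cell_probs)
      a_nuc <- .rnorm_trunc(n_nuc_k, comp$nucleus_area_mean,
                            comp$nucleus_area_sd, 8)
      r_nuc <- pmin(sqrt(a_nuc / pi), 0.8 * radii[k])
      if (n_nuc_k == 1) {
        off <- matrix(0, 1, 2)
      } else {
        # place multiple nuclei side by side inside the cell, shrinking
        # them if the cell is too small to hold them apart
        sep <- 2 * max(r_nuc) + 1.0
        if (sep / 2 + max(r_nuc) > radii[k]) {
          r_nuc <- pmin(r_nuc, (radii[k] - 0.5) / 2)
          sep <- 2 * max(r_nuc) + 0.5
        }
        ang <- runif(1, 0, 2 * pi)
        off <- (sep / 2) * cbind(c(cos(ang), -cos(ang)),
                                 c(sin(ang), -sin(ang)))
        off <- off[seq_len(n_nuc_k), , drop = FALSE]
      }
      nuc_centers <- rbind(nuc_centers,
                           sweep(off, 2, centers[k, ], `+`))
      nuc_radii <- c(nuc_radii, r_nuc)
    }
  }

  ras <- rasterize_disks(centers, radii, ps)
  true_area <- sum(ras$mask) * ps^2
  if (length(nuc_radii) > 0) {
    nras <- rasterize_disks_on(nuc_centers, nuc_radii, ps, dim(ras$mask),
                               ras$origin)
    true_nuc_area <- sum(nras) * ps^2
  } else {
    nras <- matrix(FALSE, nrow(ras$mask), ncol(ras$mask))
    true_nuc_area <- 0
  }

  structure(list(label = comp$label,
                 true_area = true_area,
                 true_cell_count = max(n_cells, if (nucleated) 1L else 0L),
                 true_nucleus_count = length(nuc_radii),
                 true_nucleus_total_area = true_nuc_area,
                 cells = cbind(centers, r = radii),
                 nuclei = if (length(nuc_radii))
                   cbind(nuc_centers, r = nuc_radii) else NULL,
                 mask = ras$mask, nuc_mask = nras,
                 origin = ras$origin),
            class = "gt_object")
}

# rasterise disks onto an existing grid (same origin convention)
rasterize_disks_on <- function(centers_um, radii_um, pixel_size, dims,
                               origin) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (k in seq_along(radii_um)) {
    cr <- origin[1] + centers_um[k, 1] / pixel_size
    cc <- origin[2] + centers_um[k, 2] / pixel_size
    rpx <- radii_um[k] / pixel_size
    rows <- max(1L, floor(cr - rpx)):min(dims[1], ceiling(cr + rpx))
    cols <- max(1L, floor(cc - rpx)):min(dims[2], ceiling(cc + rpx))
    dd <- outer((rows - cr)^2, (cols - cc)^2, `+`)
    mask[rows, cols] <- mask[rows, cols] | (dd <= rpx^2)
  }
  mask
}

#' Draw many ground-truth objects
#'
#' @param n Number of objects.
#' @param pop A [population_model()].
#' @param optics An [optics_model()].
#' @param seed Optional integer seed.
#' @return List of `gt_object`s.
#' @export
sample_objects <- function(n, pop, optics = optics_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  replicate(n, sample_object(pop, optics), simplify = FALSE)
}
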