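# Size-distribution analytics: percent-normalised histograms at the
# conventional bin widths (20 um^2 for area from 10, 0.2 for aspect
# ratio from 1, 10 um for perimeter), peak detection on smoothed
# frequencies, band fractions, cell-vs-nucleus count maps and
# total-variation distribution comparison.

.default_bins <- list(area = list(width = 20, origin = 10),
                      aspect_ratio = list(width = 0.2, origin = 1),
                      perimeter = list(width = 10, origin = 0))

#' Build a percent-normalised size histogram
#'
#' Half-open bins `[lo, hi)` of fixed width starting at the variable's
#' conventional origin; frequencies are percent of N and sum to exactly
#' 100 when N > 0.
#'
#' @param values Numeric vector; values below the origin are outside the
#'   binned range and are dropped (N counts retained values).
#' @param variable `"area"`, `"aspect_ratio"`, `"perimeter"` or any name
#'   when `bin_width`/`origin` are given.
#' @param bin_width,origin Override the per-variable bin convention.
#' @param n_bins Minimum number of bins to lay out (bins always extend
#'   to cover the data).
#' @return A `size_histogram`: `variable`, `breaks`, `mids`, `counts`,
#'   `freq_pct`, `N`.
#' @export
build_histogram <- function(values, variable = "area", bin_width = NULL,
                            origin = NULL, n_bins = 1L) {
  spec <- .default_bins[[variable]]
  if (is.null(bin_width))
    bin_width <- if (!is.null(spec)) spec$width else
      stop("bin_width required for variable '", variable, "'")
  if (is.null(origin))
    origin <- if (!is.null(spec)) spec$origin else
      stop("origin required for variable '", variable, "'")
  # the binned range starts at the origin; values below it (possible for
  # ground-truth areas of raster objects near the detection floor) fall
  # outside the distribution by convention
  values <- values[values >= origin]
  k <- max(n_bins,
           if (length(values)) floor((max(values) - origin) /
                                       bin_width) + 1L else 0L)
  breaks <- origin + bin_width * (0:k)
  counts <- if (length(values))
    tabulate(pmin(floor((values - origin) / bin_width) + 1L, k), k)
  else rep(0L, k)
  N <- length(values)
  structure(list(variable = variable, breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts,
                 freq_pct = if (N > 0) 100 * counts / N else
                   rep(0, k),
                 N = N),
            class = "size_histogram")
}

#' @export
print.size_histogram <- function(x, ...) {
  cat("<size_histogram> ", x$variable, ", N = ", x$N, ", ",
      length(x$counts), " bins [", x$breaks[1], ", ",
      x$breaks[length(x$breaks)], ")\n", sep = "")
  invisible(x)
}

#' Convert a size histogram to a data frame
#'
#' @param x A `size_histogram`.
#' @param ... Unused.
#' @return Data frame with `bin_lo`, `bin_hi`, `count`, `frequency_pct`.
#' @export
as.data.frame.size_histogram <- function(x, ...) {
  data.frame(bin_lo = x$breaks[-length(x$breaks)], bin_hi = x$breaks[-1],
             count = x$counts, frequency_pct = x$freq_pct)
}

# centred moving average, zero-padded outside the histogram range (the
# frequency outside the binned support is 0%)
.moving_average <- function(x, window) {
  half <- (window - 1) %/% 2
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  vapply(seq_len(n), function(i) mean(xp[i:(i + 2 * half)]), 0)
}

#' Detect peaks in a size histogram
#'
#' Local maxima of the (optionally moving-average-smoothed) percent
#' frequencies whose topographic prominence (height above the higher of
#' the two surrounding saddles; the frequency outside the binned range
#' counts as 0) reaches `min_prominence_pct`.
#'
#' @param hist A `size_histogram`.
#' @param smoothing_window Moving-average window in bins. Default 1 (no
#'   smoothing): at the conventional 20-um^2 area bins the red-cell and
#'   leukocyte peaks sit two bins apart, and any window >= 3 merges two
#'   peaks separated by a single low bin, which would make the band
#'   peaks of this domain unresolvable.
#' @param min_prominence_pct Minimum prominence, percentage points
#'   (default 0.2).
#' @return Data frame `bin_center`, `frequency_pct` (smoothed), ordered
#'   by bin; zero rows for flat histograms.
#' @export
detect_peaks <- function(hist, smoothing_window = 1,
                         min_prominence_pct = 0.2) {
  n <- length(hist$freq_pct)
  # a flat or empty histogram has no peaks by definition
  if (n == 0 || hist$N == 0 ||
      all(hist$freq_pct == hist$freq_pct[1]))
    return(data.frame(bin_center = numeric(0), frequency_pct = numeric(0)))
  f <- .moving_average(hist$freq_pct, smoothing_window)
  left <- c(-Inf, f[-n])
  right <- c(f[-1], -Inf)
  is_max <- f > left & f >= right
  peaks <- which(is_max)
  prom <- vapply(peaks, function(p) {
    lmin <- f[p]
    i <- p
    while (i > 1 && f[i - 1] <= f[p]) {
      i <- i - 1
      lmin <- min(lmin, f[i])
    }
    if (i == 1 && f[1] <= f[p]) lmin <- min(lmin, 0)
    rmin <- f[p]
    i <- p
    while (i < n && f[i + 1] <= f[p]) {
      i <- i + 1
      rmin <- min(rmin, f[i])
    }
    if (i == n && f[n] <= f[p]) rmin <- min(rmin, 0)
    f[p] - max(lmin, rmin)
  }, 0)
  keep <- prom >= min_prominence_pct
  data.frame(bin_center = hist$mids[peaks[keep]],
             frequency_pct = f[peaks[keep]])
}

#' Band fractions and the irregular-cell fraction
#'
#' Classifies records into area bands (with nucleus consistency) and
#' reports each band as percent of all objects, plus the irregular-cell
#' fraction: clusters as a percentage of WBC-band objects.
#'
#' @param records Data frame with `area_um2` and `nucleus_count`.
#' @param rules A [band_ruleset()].
#' @return A `band_fractions` list: `n`, `counts`, `percent`,
#'   `irregular_fraction_pct` (NA with `irregular_defined = FALSE` when
#'   there are no WBC-band objects).
#' @export
band_fractions <- function(records, rules = band_ruleset()) {
  lab <- classify(records$area_um2, records$nucleus_count, rules)
  levels <- c(rules$labels, "debris")
  counts <- table(factor(lab, levels = levels))
  n <- nrow(records)
  pct <- if (n > 0) 100 * as.numeric(counts) / n else
    rep(0, length(levels))
  n_wbc <- counts[["wbc"]]
  n_cluster <- counts[["cluster_2plus"]] + counts[["cluster_3plus"]]
  structure(list(n = n,
                 counts = setNames(as.integer(counts), levels),
                 percent = setNames(pct, levels),
                 irregular_fraction_pct =
                   if (n_wbc > 0) 100 * n_cluster / n_wbc else NA_real_,
                 irregular_defined = n_wbc > 0),
            class = "band_fractions")
}

#' Joint cell-count / nucleus-count map
#'
#' Tabulates BF cell count (x) against FL nucleus count (y). Mass below
#' the y = x diagonal flags debris-suspect objects (more apparent cells
#' than nuclei); mass above it flags multinucleate cells.
#'
#' @param records Data frame with `cell_count_bf` and `nucleus_count`.
#' @return List with `table` (data frame `cell_count_bf`,
#'   `nucleus_count`, `n`, `frequency_pct`) and the diagonal /
#'   above-diagonal / below-diagonal percent masses.
#' @export
cellcount_nucleus_map <- function(records) {
  n <- nrow(records)
  tb <- as.data.frame(table(cell_count_bf = records$cell_count_bf,
                            nucleus_count = records$nucleus_count),
                      stringsAsFactors = FALSE)
  tb <- tb[tb$Freq > 0, , drop = FALSE]
  tb$cell_count_bf <- as.integer(tb$cell_count_bf)
  tb$nucleus_count <- as.integer(tb$nucleus_count)
  names(tb)[3] <- "n"
  tb$frequency_pct <- if (n > 0) 100 * tb$n / n else numeric(nrow(tb))
  rownames(tb) <- NULL
  x <- tb$cell_count_bf
  y <- tb$nucleus_count
  list(table = tb,
       diagonal_pct = sum(tb$frequency_pct[y == x]),
       above_diagonal_pct = sum(tb$frequency_pct[y > x]),
       below_diagonal_pct = sum(tb$frequency_pct[y < x]))
}

#' Average cell size within an object
#'
#' BF area divided by the nucleus count; nucleus-free objects (debris)
#' are reported whole.
#'
#' @param area_um2 Numeric vector of BF areas.
#' @param nucleus_count Integer vector of matched nucleus counts.
#' @return Average cell (or fragment) size, um^2.
#' @export
average_cell_size <- function(area_um2, nucleus_count) {
  area_um2 / pmax(nucleus_count, 1)
}

#' Compare two size histograms
#'
#' Total-variation distance over matched bins (on proportions, in
#' [0, 1]) plus per-bin frequency differences. Histograms must share the
#' bin convention; the shorter one is zero-padded.
#'
#' @param hist_a,hist_b `size_histogram`s with equal origin and width.
#' @return List with `tv`, and `per_bin` (data frame `bin_lo`, `bin_hi`,
#'   `delta_pct` = a - b).
#' @export
compare_distributions <- function(hist_a, hist_b) {
  wa <- diff(hist_a$breaks[1:2])
  wb <- diff(hist_b$breaks[1:2])
  if (hist_a$breaks[1] != hist_b$breaks[1] || wa != wb)
    stop("histograms use different bin conventions")
  k <- max(length(hist_a$counts), length(hist_b$counts))
  pad <- function(x) c(x, rep(0, k - length(x)))
  fa <- pad(hist_a$freq_pct)
  fb <- pad(hist_b$freq_pct)
  breaks <- hist_a$breaks[1] + wa * (0:k)
  list(tv = sum(abs(fa - fb) / 100) / 2,
       per_bin = data.frame(bin_lo = breaks[-(k + 1)], bin_hi = breaks[-1],
                            delta_pct = fa - fb))
}

#' Time-course summary across day-labelled samples
#'
#' @param records_by_day Named list of record data frames (names are day
#'   tags); each needs `area_um2` and `nucleus_count`.
#' @param rules A [band_ruleset()].
#' @param variable Histogram variable (default `"area"`); records must
#'   carry the matching column (`area_um2`, `aspect_ratio`,
#'   `perimeter_um`).
#' @return A `timecourse_summary`: per-day histograms and band
#'   fractions, and the symmetric pairwise total-variation matrix.
#' @export
timecourse_summary <- function(records_by_day, rules = band_ruleset(),
                               variable = "area") {
  stopifnot(length(records_by_day) >= 1, !is.null(names(records_by_day)))
  col <- switch(variable, area = "area_um2", perimeter = "perimeter_um",
                variable)
  hists <- lapply(records_by_day, function(r)
    build_histogram(r[[col]], variable))
  fracs <- lapply(records_by_day, band_fractions, rules = rules)
  k <- length(hists)
  tv <- matrix(0, k, k, dimnames = list(names(hists), names(hists)))
  if (k > 1)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      tv[i, j] <- tv[j, i] <- compare_distributions(hists[[i]],
                                                    hists[[j]])$tv
  structure(list(histograms = hists, band_fractions = fracs,
                 tv_distance = tv),
            class = "timecourse_summary")
}
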