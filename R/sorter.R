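# Rule-based classification and the virtual sorter: area-band labels
# cross-checked against nucleus counts, a strict area trigger, a
# constant-displacement pulse model and the two-outlet routing contract.

#' Area-band classification rules
#'
#' Bands in um^2: rbc_debris [10,30), unclassified_small [30,50),
#' wbc [50,70), intermediate [70,90), large_single [90,150),
#' cluster_2plus [150,270), cluster_3plus [270,Inf). Objects with no
#' matched nucleus are debris regardless of size; cluster bands demand a
#' consistent nucleus count (>= 2 and >= 3 respectively), otherwise the
#' object is a debris aggregate.
#'
#' @param edges Increasing band edges, um^2.
#' @param labels Band labels, one per edge; band i spans
#'   `[edges[i], edges[i+1])` and the last band is right-open to
#'   infinity.
#' @param require_nuclei Apply the nucleus-consistency switches.
#' @return A `band_ruleset`.
#' @export
band_ruleset <- function(edges = c(10, 30, 50, 70, 90, 150, 270),
                         labels = c("rbc_debris", "unclassified_small",
                                    "wbc", "intermediate", "large_single",
                                    "cluster_2plus", "cluster_3plus"),
                         require_nuclei = TRUE) {
  stopifnot(length(labels) == length(edges),
            all(diff(edges) > 0))
  structure(list(edges = edges, labels = labels,
                 require_nuclei = require_nuclei),
            class = "band_ruleset")
}

#' Classify objects from area and nucleus count
#'
#' Vectorised total function over area >= 10 um^2 and nucleus_count >= 0:
#' zero nuclei means debris whatever the size; otherwise the area band
#' applies, with cluster bands downgraded to debris when the nucleus
#' count contradicts them.
#'
#' @param area_um2 Numeric vector of BF areas.
#' @param nucleus_count Integer vector of matched nucleus counts.
#' @param rules A [band_ruleset()].
#' @return Character vector of labels (including `"debris"`).
#' @export
classify <- function(area_um2, nucleus_count, rules = band_ruleset()) {
  stopifnot(length(area_um2) == length(nucleus_count))
  band <- findInterval(area_um2, rules$edges)
  band[band < 1] <- 1L
  lab <- rules$labels[band]
  if (rules$require_nuclei) {
    lab[nucleus_count == 0] <- "debris"
    lab[lab == "cluster_2plus" & nucleus_count < 2] <- "debris"
    lab[lab == "cluster_3plus" & nucleus_count < 3] <- "debris"
  }
  lab
}

#' Sort trigger on BF area
#'
#' TRUE iff the area strictly exceeds the threshold (default 300 um^2).
#'
#' @param area_um2 Numeric vector of BF areas.
#' @param area_threshold_um2 Trigger threshold, um^2.
#' @return Logical vector.
#' @export
trigger_sort <- function(area_um2, area_threshold_um2 = 300) {
  area_um2 > area_threshold_um2
}

#' Sorting pulse parameters
#'
#' @param voltage_V DC pulse voltage (metadata; default 40).
#' @param duration_us Pulse length, microseconds (default 100).
#' @param displacement_um Modelled lateral shift per pulse, um
#'   (default 10; no electrokinetic force model is attempted).
#' @return A `sort_pulse`.
#' @export
sort_pulse <- function(voltage_V = 40, duration_us = 100,
                       displacement_um = 10) {
  stopifnot(duration_us > 0, displacement_um >= 0)
  structure(list(voltage_V = voltage_V, duration_us = duration_us,
                 displacement_um = displacement_um),
            class = "sort_pulse")
}

#' Sorting channel geometry
#'
#' @param width_um Channel width (default 50).
#' @param height_um Channel height (metadata; default 22).
#' @param delta_um Routing threshold: lateral shift beyond which an
#'   object leaves the centre stream into the collection outlet
#'   (default 8.3).
#' @param electrode_width_um Gel electrode width (metadata; default 13).
#' @return A `channel_geometry`.
#' @export
channel_geometry <- function(width_um = 50, height_um = 22,
                             delta_um = 8.3, electrode_width_um = 13) {
  if (!(delta_um > 0 && delta_um < width_um / 2))
    stop("delta_um must lie in (0, width_um/2)")
  structure(list(width_um = width_um, height_um = height_um,
                 delta_um = delta_um,
                 electrode_width_um = electrode_width_um),
            class = "channel_geometry")
}

#' Lateral displacement produced by a pulse decision
#'
#' @param triggered Logical vector.
#' @param pulse A [sort_pulse()].
#' @return Displacement in um: `pulse$displacement_um` where triggered,
#'   else 0.
#' @export
apply_pulse <- function(triggered, pulse = sort_pulse()) {
  ifelse(triggered, pulse$displacement_um, 0)
}

#' Two-outlet routing
#'
#' Collection iff the displacement strictly exceeds `delta_um` ("more
#' than" the 8.3-um offset from the channel centre); everything else
#' flows to discard.
#'
#' @param displacement_um Numeric vector of lateral shifts.
#' @param geometry A [channel_geometry()].
#' @return Character vector, `"collection"` or `"discard"`.
#' @export
route_outlet <- function(displacement_um, geometry = channel_geometry()) {
  ifelse(displacement_um > geometry$delta_um, "collection", "discard")
}

#' Run the virtual sorter over a table of object records
#'
#' @param records Data frame with at least `area_um2`; optional
#'   `object_id`, `frame`, `nucleus_count`.
#' @param rules A [band_ruleset()] (used for the purity summary).
#' @param pulse A [sort_pulse()].
#' @param geometry A [channel_geometry()].
#' @param area_threshold_um2 Trigger threshold, um^2 (default 300).
#' @param truth_labels Optional character vector of ground-truth labels
#'   (same length as `records`); enables yield/purity.
#' @param target_labels Ground-truth classes counted as targets.
#' @return List with `events` (one row per record: trigger decision,
#'   pulse parameters, displacement, outlet) and `summary` (n_total,
#'   n_triggered, n_collection, yield, purity).
#' @export
run_sorting <- function(records, rules = band_ruleset(),
                        pulse = sort_pulse(),
                        geometry = channel_geometry(),
                        area_threshold_um2 = 300,
                        truth_labels = NULL,
                        target_labels = "cluster") {
  n <- nrow(records)
  triggered <- trigger_sort(records$area_um2, area_threshold_um2)
  displacement <- apply_pulse(triggered, pulse)
  outlet <- route_outlet(displacement, geometry)
  events <- data.frame(
    object_id = if (!is.null(records$object_id)) records$object_id
                else seq_len(n),
    frame = if (!is.null(records$frame)) records$frame
            else rep(NA_integer_, n),
    triggered = triggered,
    voltage_V = ifelse(triggered, pulse$voltage_V, NA_real_),
    duration_us = ifelse(triggered, pulse$duration_us, NA_real_),
    displacement_um = displacement,
    outlet = outlet,
    decision_latency_frames = rep(1L, n))
  yield <- purity <- NA_real_
  if (!is.null(truth_labels)) {
    stopifnot(length(truth_labels) == n)
    is_target <- truth_labels %in% target_labels
    if (any(is_target))
      yield <- mean(outlet[is_target] == "collection")
    if (any(outlet == "collection"))
      purity <- mean(is_target[outlet == "collection"])
  }
  list(events = events,
       summary = list(n_total = n,
                      n_triggered = sum(triggered),
                      n_collection = sum(outlet == "collection"),
                      yield = yield, purity = purity))
}
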