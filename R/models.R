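#' Optical/camera model of the dual-view acquisition
#'
#' Describes how the single CCD sensor sees the microchannel: one half of
#' the sensor records the bright-field (BF) view, the other half records
#' the fluorescence (FL) view of the same field at the same pixel
#' coordinates. Intensities are 8-bit (0--255).
#'
#' @param pixel_size Physical size of one pixel, micrometres. Default 0.5
#'   (makes a 50-um channel 100 px wide).
#' @param frame_width,frame_height Size in pixels of one channel view
#'   (the combined dual-view frame is `frame_height x 2*frame_width`).
#' @param bf_background_level BF background intensity (illuminated field).
#' @param fl_background_level FL background intensity (dark field).
#' @param bf_contrast Intensity drop of an object below the BF background.
#' @param fl_nucleus_peak Intensity of stained-nucleus pixels above the FL
#'   background. Must exceed 16, the 4-bit recognition floor.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise,
#'   8-bit intensity units.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(pixel_size = 0.5,
                         frame_width = 400L,
                         frame_height = 100L,
                         bf_background_level = 180,
                         fl_background_level = 8,
                         bf_contrast = 60,
                         fl_nucleus_peak = 80,
                         noise_sd = 2) {
  stopifnot(pixel_size > 0, frame_width >= 8, frame_height >= 8)
  lv <- c(bf_background_level, fl_background_level, bf_contrast,
          fl_nucleus_peak)
  if (any(lv < 0 | lv > 255))
    stop("intensity parameters must lie in [0, 255]")
  if (fl_nucleus_peak <= 16)
    stop("fl_nucleus_peak must exceed the 4-bit floor (16 of 256 steps)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(pixel_size = pixel_size,
                 frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 bf_background_level = bf_background_level,
                 fl_background_level = fl_background_level,
                 bf_contrast = bf_contrast,
                 fl_nucleus_peak = fl_nucleus_peak,
                 noise_sd = noise_sd),
            class = "optics_model")
}

#' Hydrodynamically focused stream model
#'
#' Parameters of the focused sample stream inside the sorting channel.
#' Hydrodynamic focusing centres objects on a lane along the channel
#' axis, spaces neighbours apart, and aligns them with the flow; here it
#' is modelled as a row-centred lane with Gaussian jitter and a minimum
#' centre-to-centre spacing between neighbouring objects.
#'
#' @param frame_rate Acquisition rate, frames per second (default 200).
#' @param arrival_rate Expected number of objects entering the view per
#'   frame (Poisson).
#' @param lane_center Pixel row of the focused lane (default: mid-height).
#' @param lane_jitter_sd Lateral jitter of object centres, micrometres.
#' @param flow_speed Flow velocity, mm/s (metadata only; default 3).
#' @param channel_width Channel width, micrometres (default 50).
#' @param channel_height Channel height, micrometres (metadata; default 22).
#' @param min_spacing_um Minimum centre-to-centre spacing between
#'   neighbouring objects along the flow axis, micrometres.
#' @param frame_height Used only to derive the default `lane_center`.
#' @return An object of class `stream_model`.
#' @export
stream_model <- function(frame_rate = 200,
                         arrival_rate = 2,
                         lane_center = frame_height / 2,
                         lane_jitter_sd = 2,
                         flow_speed = 3,
                         channel_width = 50,
                         channel_height = 22,
                         min_spacing_um = 35,
                         frame_height = 100L) {
  stopifnot(frame_rate > 0, arrival_rate >= 0, lane_jitter_sd >= 0,
            min_spacing_um > 0, channel_width > 0)
  if (lane_center < 0 || lane_center >= frame_height)
    stop("lane_center must lie within [0, frame_height)")
  structure(list(frame_rate = frame_rate,
                 arrival_rate = arrival_rate,
                 lane_center = lane_center,
                 lane_jitter_sd = lane_jitter_sd,
                 flow_speed = flow_speed,
                 channel_width = channel_width,
                 channel_height = channel_height,
                 min_spacing_um = min_spacing_um),
            class = "stream_model")
}

#' Background model: pre-recorded reference frames per channel
#'
#' The analysis pipeline removes a pre-recorded background image from each
#' channel before thresholding. For the simulator the reference frames are
#' the noise-free uniform backgrounds of the optics model.
#'
#' @param optics An [optics_model()].
#' @return List with `bf_background` and `fl_background` matrices, class
#'   `background_model`.
#' @export
background_model <- function(optics) {
  stopifnot(inherits(optics, "optics_model"))
  h <- optics$frame_height
  w <- optics$frame_width
  structure(list(
    bf_background = matrix(optics$bf_background_level, h, w),
    fl_background = matrix(optics$fl_background_level, h, w)),
    class = "background_model")
}

#' @export
print.optics_model <- function(x, ...) {
  cat("<optics_model> ", x$frame_height, "x", x$frame_width,
      " px/view, ", x$pixel_size, " um/px, BF bg ", x$bf_background_level,
      " (contrast ", x$bf_contrast, "), FL bg ", x$fl_background_level,
      " (nucleus peak ", x$fl_nucleus_peak, "), noise sd ", x$noise_sd,
      "\n", sep = "")
  invisible(x)
}

#' @export
print.stream_model <- function(x, ...) {
  cat("<stream_model> ", x$frame_rate, " fps, arrival rate ",
      x$arrival_rate, "/frame, lane row ", x$lane_center,
      " (jitter sd ", x$lane_jitter_sd, " um), min spacing ",
      x$min_spacing_um, " um\n", sep = "")
  invisible(x)
}
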