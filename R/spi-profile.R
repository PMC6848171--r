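#' Classify SPI pixels below the water-maerl interface
#'
#' Assigns every pixel of an SPI cross-section image to one of four classes:
#' `above_interface`, `live` maerl, `dead` maerl or `interstice`. Pixels above
#' the manually traced water-maerl interface are never analyzed. Below the
#' interface, a dark pixel (channel mean below `dark_threshold`) is interstitial
#' space (shadowed voids or sediment); among the remaining pale maerl pixels a
#' single red-channel threshold separates pigmented live thalli
#' (R > `red_threshold`) from bleached dead ones.
#'
#' @param image numeric array `height x width x 3`, 8-bit RGB values in 0-255.
#' @param trace interface trace: integer vector of length `width`, the number of
#'   water rows above the interface in each pixel column (0 means the interface
#'   sits at the very top). Must satisfy `0 <= trace <= height - 1`.
#' @param red_threshold red-channel value (0-255) separating live from dead
#'   maerl.
#' @param dark_threshold brightness (mean of R, G, B; 0-255) below which a
#'   below-interface pixel is interstitial space.
#' @return An integer matrix `height x width` of class codes (0 =
#'   above_interface, 1 = live, 2 = dead, 3 = interstice) with attribute
#'   `classes` naming the codes, of S3 class `"label_mask"`.
#' @seealso [live_dead_ratio()], [vertical_profiles()], [analyze_spi_image()]
#' @export
classify_pixels <- function(image, trace, red_threshold = 185,
                            dark_threshold = 95) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3L] == 3L)
  stop_if_not_scalar(red_threshold, "red_threshold", 0, 255)
  stop_if_not_scalar(dark_threshold, "dark_threshold", 0, 255)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  trace <- validate_trace(trace, w, h)

  brightness <- (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
  mask <- matrix(.CLASS_DEAD, h, w)
  mask[brightness < dark_threshold] <- .CLASS_INTERSTICE
  live <- image[, , 1L] > red_threshold & brightness >= dark_threshold
  mask[live] <- .CLASS_LIVE
  above <- (.row(c(h, w)) - 1) < matrix(trace, h, w, byrow = TRUE)
  mask[above] <- .CLASS_ABOVE
  mask <- matrix(as.integer(mask), h, w)
  attr(mask, "classes") <- .class_labels
  class(mask) <- c("label_mask", class(mask))
  mask
}

validate_trace <- function(trace, width, height) {
  if (length(trace) != width)
    stop("interface trace length (", length(trace),
         ") does not match image width (", width, ")", call. = FALSE)
  if (any(!is.finite(trace)) || any(trace < 0) || any(trace > height - 1))
    stop("interface trace rows must lie within [0, height - 1]", call. = FALSE)
  as.numeric(trace)
}

#' Interface rugosity of an SPI trace
#'
#' Rugosity is the summed absolute difference in interface row position between
#' contiguous pixel columns, divided by the full image width in pixels. A flat
#' interface has rugosity 0; rougher bed surfaces give larger values. The
#' measure is invariant to vertical translation of the whole trace.
#'
#' @inheritParams classify_pixels
#' @param width_px image width in pixels; defaults to `length(trace)`.
#' @return Dimensionless rugosity (pixels of vertical relief per pixel of
#'   width).
#' @examples
#' interface_rugosity(rep(200, 100))            # flat: 0
#' interface_rugosity(rep(c(100, 110), 50))     # sawtooth of step 10: 9.9
#' @export
interface_rugosity <- function(trace, width_px = length(trace)) {
  stopifnot(width_px >= 2L, length(trace) == width_px)
  sum(abs(diff(as.numeric(trace)))) / width_px
}

#' SPI penetration depth
#'
#' Vertical distance from the mean interface position to the bottom of the
#' image, in centimetres. Penetration depth is a proxy for substratum
#' compaction: the prism sinks deeper into a soft, well-structured bed.
#'
#' @inheritParams classify_pixels
#' @param height_px image height in pixels.
#' @param scale_cm_per_px physical pixel size in cm.
#' @return Penetration depth in cm.
#' @export
penetration_depth <- function(trace, height_px, scale_cm_per_px) {
  stop_if_not_scalar(scale_cm_per_px, "scale_cm_per_px", lo = 1e-12)
  (height_px - mean(as.numeric(trace))) * scale_cm_per_px
}

#' Live/dead maerl area ratio
#'
#' Ratio of the image area classified as live maerl to the area classified as
#' dead maerl, a vitality proxy. When no dead maerl is detected the ratio is
#' undefined and flagged, so that station-level aggregation can exclude the
#' image rather than propagate an infinity.
#'
#' @param mask a `label_mask` from [classify_pixels()].
#' @return A list with elements `live_px`, `dead_px`, `interstice_px`,
#'   `ratio` (NA when undefined) and `defined` (logical).
#' @export
live_dead_ratio <- function(mask) {
  counts <- tabulate(mask[mask != .CLASS_ABOVE] , nbins = 3L)
  live <- counts[.CLASS_LIVE]; dead <- counts[.CLASS_DEAD]
  list(live_px = live, dead_px = dead, interstice_px = counts[.CLASS_INTERSTICE],
       ratio = if (dead > 0) live / dead else NA_real_,
       defined = dead > 0)
}

#' Interface-flattened vertical class profiles
#'
#' Shifts every pixel column so that its interface sits at depth 0, then bins
#' pixels into half-open depth bins (default 5 mm) and reports the percentage
#' of live maerl, dead maerl and interstitial space among each bin's pixels.
#' A pixel's depth is taken at its top edge: the first below-interface pixel of
#' a column has depth 0. Columns contribute only down to the image bottom, so
#' the deepest bins may be ragged; bins with no pixels are flagged missing
#' (NA percentages).
#'
#' @inheritParams classify_pixels
#' @param mask a `label_mask` from [classify_pixels()].
#' @param scale_cm_per_px physical pixel size in cm.
#' @param bin_cm vertical bin size in cm (default 0.5, i.e. 5 mm).
#' @param max_depth_cm optional maximum depth; bins starting at or beyond it are
#'   dropped.
#' @return A data.frame with one row per bin: `bin` (0-based index),
#'   `depth_from_cm`, `depth_to_cm`, `n_px`, `pct_live`, `pct_dead`,
#'   `pct_interstice`. Percentages sum to 100 in every non-empty bin.
#' @export
vertical_profiles <- function(mask, trace, scale_cm_per_px, bin_cm = 0.5,
                              max_depth_cm = NULL) {
  stop_if_not_scalar(bin_cm, "bin_cm", lo = 1e-12)
  stop_if_not_scalar(scale_cm_per_px, "scale_cm_per_px", lo = 1e-12)
  h <- nrow(mask); w <- ncol(mask)
  trace <- validate_trace(trace, w, h)

  depth_px <- .row(c(h, w)) - 1 - matrix(trace, h, w, byrow = TRUE)
  below <- depth_px >= 0
  if (!identical(unname(below), unname(unclass(mask) != .CLASS_ABOVE)))
    stop("mask and trace disagree on the above-interface region", call. = FALSE)
  bin <- floor(depth_px[below] * scale_cm_per_px / bin_cm + 1e-9)
  cls <- unclass(mask)[below]
  n_bins_total <- max(bin) + 1L
  n_bins <- if (is.null(max_depth_cm)) n_bins_total else
    min(n_bins_total, ceiling(max_depth_cm / bin_cm - 1e-9))

  counts <- matrix(0L, n_bins, 3L)
  keep <- bin < n_bins
  tab <- table(factor(bin[keep], levels = 0:(n_bins - 1L)),
               factor(cls[keep], levels = 1:3))
  counts <- matrix(as.integer(tab), n_bins, 3L)
  n_px <- rowSums(counts)
  pct <- counts / ifelse(n_px > 0, n_px, NA_real_) * 100
  data.frame(bin = 0:(n_bins - 1L),
             depth_from_cm = (0:(n_bins - 1L)) * bin_cm,
             depth_to_cm = (1:n_bins) * bin_cm,
             n_px = n_px,
             pct_live = pct[, 1L], pct_dead = pct[, 2L],
             pct_interstice = pct[, 3L])
}

#' All per-image SPI metrics in one call
#'
#' Convenience wrapper running [classify_pixels()], [interface_rugosity()],
#' [penetration_depth()], [live_dead_ratio()] and [vertical_profiles()] on one
#' image + trace pair.
#'
#' @inheritParams classify_pixels
#' @inheritParams vertical_profiles
#' @return A list with `metrics` (one-row data.frame: rugosity,
#'   penetration_cm, live_px, dead_px, interstice_px, live_dead_ratio,
#'   ratio_defined), `profiles` (data.frame from [vertical_profiles()]) and
#'   `mask`.
#' @export
analyze_spi_image <- function(image, trace, scale_cm_per_px,
                              red_threshold = 185, dark_threshold = 95,
                              bin_cm = 0.5, max_depth_cm = NULL) {
  mask <- classify_pixels(image, trace, red_threshold, dark_threshold)
  areas <- live_dead_ratio(mask)
  list(
    metrics = data.frame(
      rugosity = interface_rugosity(trace),
      penetration_cm = penetration_depth(trace, nrow(mask), scale_cm_per_px),
      live_px = areas$live_px, dead_px = areas$dead_px,
      interstice_px = areas$interstice_px,
      live_dead_ratio = areas$ratio, ratio_defined = areas$defined),
    profiles = vertical_profiles(mask, trace, scale_cm_per_px, bin_cm,
                                 max_depth_cm),
    mask = mask)
}

#' Fit the live/dead red-channel threshold on labelled pixels
#'
#' The red threshold is normally set by expert judgement; given labelled
#' calibration pixels this helper chooses the threshold minimizing
#' live-vs-dead misclassification by scanning candidate integer thresholds.
#'
#' @param red_values red-channel values (0-255) of calibration pixels.
#' @param is_live logical, TRUE where the pixel is known live maerl.
#' @return The integer threshold minimizing misclassification (live iff
#'   red > threshold); ties resolved toward the midpoint of the optimal range.
#' @export
calibrate_red_threshold <- function(red_values, is_live) {
  stopifnot(length(red_values) == length(is_live), any(is_live), any(!is_live))
  cand <- 0:255
  err <- vapply(cand, function(t)
    sum(is_live & red_values <= t) + sum(!is_live & red_values > t), 0)
  best <- cand[err == min(err)]
  as.integer(round(mean(range(best))))
}
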