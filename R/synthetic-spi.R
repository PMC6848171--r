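#' Class color model for synthetic SPI images
#'
#' Defines the per-class RGB color distributions and the classification
#' thresholds a synthetic SPI scene is built around. Each class draws its
#' channels from independent Gaussians (mean per channel, common `channel_sd`)
#' clipped to 0-255 and rounded to 8 bits. The constructor enforces
#' separability at `channel_sd = 0`: the live red mean must exceed
#' `red_threshold`, which must exceed the dead red mean, and the interstice
#' brightness mean must fall below `dark_threshold`, itself below the live and
#' dead brightness means.
#'
#' @param live_rgb,dead_rgb,interstice_rgb length-3 channel means (0-255).
#' @param channel_sd non-negative Gaussian spread applied to every channel.
#' @param red_threshold red-channel live/dead threshold.
#' @param dark_threshold brightness threshold below which a pixel is
#'   interstice.
#' @param water_rgb color of the water region above the interface (excluded
#'   from all metrics).
#' @return An object of class `"color_model"`.
#' @export
color_model <- function(live_rgb = c(220, 130, 130),
                        dead_rgb = c(150, 150, 150),
                        interstice_rgb = c(40, 40, 40),
                        channel_sd = 8,
                        red_threshold = 185,
                        dark_threshold = 95,
                        water_rgb = c(25, 50, 110)) {
  for (v in list(live_rgb, dead_rgb, interstice_rgb, water_rgb))
    stopifnot(length(v) == 3L, all(v >= 0), all(v <= 255))
  stop_if_not_scalar(channel_sd, "channel_sd", 0)
  stop_if_not_scalar(red_threshold, "red_threshold", 0, 255)
  stop_if_not_scalar(dark_threshold, "dark_threshold", 0, 255)
  if (!(live_rgb[1L] > red_threshold && red_threshold > dead_rgb[1L]))
    stop("need live red mean > red_threshold > dead red mean", call. = FALSE)
  br <- function(v) mean(v)
  if (!(br(interstice_rgb) < dark_threshold &&
        dark_threshold < min(br(live_rgb), br(dead_rgb))))
    stop("need interstice brightness < dark_threshold < live/dead brightness",
         call. = FALSE)
  structure(list(live_rgb = live_rgb, dead_rgb = dead_rgb,
                 interstice_rgb = interstice_rgb, water_rgb = water_rgb,
                 channel_sd = channel_sd, red_threshold = red_threshold,
                 dark_threshold = dark_threshold),
            class = "color_model")
}

#' Interface shape specifications
#'
#' Constructors for the bounded row-function-of-column shapes a synthetic
#' water-maerl interface can take: constant, linear ramp, sum of sinusoids, or
#' a reflected random walk. All produce integer row traces (number of water
#' rows per column).
#'
#' @param row,from,to,base interface row positions (0-based water-row counts).
#' @param amplitude,periods vectors of sinusoid amplitudes (rows) and periods
#'   (fractions of image width).
#' @param step_sd Gaussian step magnitude of the random walk (rows).
#' @param band half-width of the reflection band around `base` (rows).
#' @return A specification list consumed by [generate_spi_image()].
#' @name interface_spec
NULL

#' @rdname interface_spec
#' @export
interface_flat <- function(row) structure(list(type = "flat", row = row),
                                          class = "interface_spec")

#' @rdname interface_spec
#' @export
interface_ramp <- function(from, to) structure(list(type = "ramp", from = from,
                                                    to = to),
                                               class = "interface_spec")

#' @rdname interface_spec
#' @export
interface_sine <- function(base, amplitude, periods)
  structure(list(type = "sine", base = base, amplitude = amplitude,
                 periods = periods), class = "interface_spec")

#' @rdname interface_spec
#' @export
interface_walk <- function(base, step_sd, band = 40)
  structure(list(type = "walk", base = base, step_sd = step_sd, band = band),
            class = "interface_spec")

realize_trace <- function(spec, width_px, height_px) {
  if (is.numeric(spec)) {
    tr <- spec
  } else {
    tr <- switch(spec$type,
      flat = rep(spec$row, width_px),
      ramp = seq(spec$from, spec$to, length.out = width_px),
      sine = {
        x <- seq_len(width_px) - 1
        y <- rep(spec$base, width_px)
        for (i in seq_along(spec$amplitude))
          y <- y + spec$amplitude[i] *
            sin(2 * pi * x / (spec$periods[i] * width_px))
        y
      },
      walk = {
        steps <- rnorm(width_px - 1L, 0, spec$step_sd)
        y <- spec$base + c(0, cumsum(steps))
        # reflect into [base - band, base + band]
        lo <- spec$base - spec$band; hi <- spec$base + spec$band
        span <- hi - lo
        y <- lo + abs(((y - lo) %% (2 * span)) - span)
        y
      },
      stop("unknown interface spec type: ", spec$type))
    tr <- round(tr)
  }
  if (any(tr < 0) || any(tr > height_px - 1))
    stop("interface rows fall outside [0, height)", call. = FALSE)
  as.numeric(tr)
}

#' Generate a synthetic SPI cross-section image with known ground truth
#'
#' Builds an RGB SPI scene: water above a prescribed interface, and below it a
#' mosaic of live maerl, dead maerl and interstitial-space pixels whose
#' composition follows per-depth-band target fractions. Class proportions are
#' allocated exactly per depth bin (largest-remainder rounding) and positions
#' shuffled within the bin, so the stored ground truth is attained by
#' construction. Pixel colors are drawn from the color model; at
#' `channel_sd = 0` classification with the model's thresholds recovers the
#' truth mask for 100% of below-interface pixels.
#'
#' @param width_px,height_px image size; defaults give the 14.5 x 21.8 cm
#'   field of a typical SPI frame at `scale_cm_per_px = 0.02`.
#' @param scale_cm_per_px physical pixel size in cm.
#' @param interface an [interface_spec] (or an explicit numeric trace).
#' @param composition matrix or data.frame with columns live, dead, interstice:
#'   one row per consecutive depth band of `band_cm` (the last band extends to
#'   the image bottom). Each row must sum to 1.
#' @param color_model a [color_model()].
#' @param band_cm thickness of the composition bands in cm (default 0.5).
#' @param seed integer seed; identical seeds and arguments give byte-identical
#'   output.
#' @return A list of class `"spi_scene"`: `image` (H x W x 3 array, 0-255),
#'   `trace`, `scale_cm_per_px`, and `truth` (class `"scene_truth"`: the true
#'   label `mask`, per-bin `profiles` fractions, `rugosity`,
#'   `penetration_cm`, pixel areas and live/dead ratio).
#' @export
generate_spi_image <- function(width_px = 725, height_px = 1090,
                               scale_cm_per_px = 0.02,
                               interface = interface_flat(200),
                               composition = c(live = 0.5, dead = 0.3,
                                               interstice = 0.2),
                               color_model = maerlspi::color_model(),
                               band_cm = 0.5, seed = NULL) {
  stopifnot(width_px >= 2L, height_px >= 2L)
  comp <- as.matrix(rbind(composition))
  if (ncol(comp) != 3L) stop("composition needs 3 columns (live, dead, interstice)")
  if (any(comp < 0) || any(abs(rowSums(comp) - 1) > 1e-9))
    stop("composition fractions must be non-negative and sum to 1 per band",
         call. = FALSE)

  with_seed(seed, {
    trace <- realize_trace(interface, width_px, height_px)

    depth_px <- .row(c(height_px, width_px)) - 1 -
      matrix(trace, height_px, width_px, byrow = TRUE)
    below <- depth_px >= 0
    bin <- floor(depth_px * scale_cm_per_px / band_cm + 1e-9)
    bin[!below] <- NA

    mask <- matrix(.CLASS_ABOVE, height_px, width_px)
    for (b in sort(unique(bin[below]))) {
      idx <- which(!is.na(bin) & bin == b)
      fr <- comp[min(b + 1L, nrow(comp)), ]
      counts <- allocate_counts(length(idx), fr)
      labels <- rep(c(.CLASS_LIVE, .CLASS_DEAD, .CLASS_INTERSTICE), counts)
      # sample.int, not sample(labels): a one-pixel bin must not trigger
      # base R's scalar-sample expansion
      mask[idx] <- labels[sample.int(length(labels))]
    }

    img <- render_mask(mask, color_model)
    truth <- scene_truth(mask, trace, scale_cm_per_px, band_cm)
    structure(list(image = img, trace = trace,
                   scale_cm_per_px = scale_cm_per_px, truth = truth),
              class = "spi_scene")
  })
}

# Paint an RGB image from a label mask using the color model distributions.
render_mask <- function(mask, cm) {
  h <- nrow(mask); w <- ncol(mask)
  img <- array(0, dim = c(h, w, 3L))
  means <- rbind(cm$water_rgb, cm$live_rgb, cm$dead_rgb, cm$interstice_rgb)
  idx <- unclass(mask) + 1L
  for (ch in 1:3) {
    plane <- matrix(means[idx, ch], h, w)
    if (cm$channel_sd > 0)
      plane <- plane + rnorm(h * w, 0, cm$channel_sd)
    img[, , ch] <- pmin(255, pmax(0, round(plane)))
  }
  img
}

# Recompute all ground-truth quantities from a label mask + trace using the
# closed formulas, so stored truths are self-consistent by construction.
scene_truth <- function(mask, trace, scale_cm_per_px, band_cm = 0.5) {
  h <- nrow(mask); w <- ncol(mask)
  counts <- tabulate(mask[mask != .CLASS_ABOVE], nbins = 3L)
  depth_px <- .row(c(h, w)) - 1 - matrix(trace, h, w, byrow = TRUE)
  below <- depth_px >= 0
  bin <- floor(depth_px[below] * scale_cm_per_px / band_cm + 1e-9)
  cls <- unclass(mask)[below]
  tab <- table(factor(bin, levels = 0:max(bin)), factor(cls, levels = 1:3))
  frac <- as.matrix(tab) / rowSums(tab)
  structure(list(
    mask = mask, trace = trace,
    profiles = data.frame(bin = 0:max(bin),
                          depth_from_cm = (0:max(bin)) * band_cm,
                          frac_live = frac[, 1L], frac_dead = frac[, 2L],
                          frac_interstice = frac[, 3L],
                          n_px = as.integer(rowSums(tab))),
    rugosity = sum(abs(diff(trace))) / w,
    penetration_cm = (h - mean(trace)) * scale_cm_per_px,
    live_px = counts[1L], dead_px = counts[2L], interstice_px = counts[3L],
    live_dead_ratio = if (counts[2L] > 0) counts[1L] / counts[2L] else NA_real_),
    class = "scene_truth")
}
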