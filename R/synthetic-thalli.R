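#' Polygon constructors for synthetic thalli
#'
#' Small library of silhouette polygons with analytically known perimeter,
#' area and solidity, used as ground truth for the raster morphometrics.
#' Coordinates are in pixel units; `center` places the shape on the canvas.
#'
#' @param side,width,height,radius dimensions in pixels.
#' @param arm arm length of the plus sign in pixels (the plus is a 3x3 block of
#'   `arm`-sided squares minus its corners).
#' @param n_points number of star spikes.
#' @param r_outer,r_inner outer/inner vertex radii of the star.
#' @param n_vertices number of vertices approximating a disk.
#' @param center length-2 (x, y) center.
#' @return A 2-column matrix of vertices (counter-clockwise).
#' @name thallus_polygons
NULL

#' @rdname thallus_polygons
#' @export
poly_rect <- function(width, height, center = c(0, 0)) {
  w2 <- width / 2; h2 <- height / 2
  cbind(x = center[1L] + c(-w2, w2, w2, -w2),
        y = center[2L] + c(-h2, -h2, h2, h2))
}

#' @rdname thallus_polygons
#' @export
poly_square <- function(side, center = c(0, 0)) poly_rect(side, side, center)

#' @rdname thallus_polygons
#' @export
poly_plus <- function(arm, center = c(0, 0)) {
  a <- arm / 2
  x <- c(-a, a, a, 3 * a, 3 * a, a, a, -a, -a, -3 * a, -3 * a, -a)
  y <- c(-3 * a, -3 * a, -a, -a, a, a, 3 * a, 3 * a, a, a, -a, -a)
  cbind(x = center[1L] + x, y = center[2L] + y)
}

#' @rdname thallus_polygons
#' @export
poly_star <- function(n_points, r_outer, r_inner, center = c(0, 0)) {
  stopifnot(n_points >= 3L, r_inner > 0, r_inner < r_outer)
  ang <- (0:(2 * n_points - 1)) * pi / n_points - pi / 2
  r <- rep(c(r_outer, r_inner), n_points)
  cbind(x = center[1L] + r * cos(ang), y = center[2L] + r * sin(ang))
}

#' @rdname thallus_polygons
#' @export
poly_disk <- function(radius, center = c(0, 0), n_vertices = 256L) {
  ang <- (0:(n_vertices - 1)) * 2 * pi / n_vertices
  cbind(x = center[1L] + radius * cos(ang),
        y = center[2L] + radius * sin(ang))
}

# Analytic shape truth for a polygon: perimeter, area, convex-hull area,
# solidity.
polygon_truth <- function(xy) {
  hull <- hull_area(xy)
  area <- polygon_area(xy)
  data.frame(perimeter = polygon_perimeter(xy), area = area,
             convex_area = hull, solidity = area / hull)
}

#' Generate a synthetic thalli silhouette image
#'
#' Rasterizes pale filled polygons onto a matt black background, as maerl
#' thalli photographed for morphometric analysis, and returns the analytic
#' per-shape ground truth (perimeter, area, solidity computed on the
#' continuous polygon). A pixel belongs to a shape when its center falls
#' inside the polygon. Shapes must not overlap (per-object truth would be
#' ambiguous); overlap at raster level is rejected.
#'
#' @param shapes list of polygons (2-column vertex matrices, pixel units, in
#'   canvas coordinates with x to the right and y downwards).
#' @param canvas_px `c(width, height)` of the canvas in pixels.
#' @param foreground,background mean 8-bit intensities of thallus and
#'   background pixels.
#' @param intensity_sd Gaussian intensity noise (0 for a clean silhouette).
#' @param seed integer seed for the intensity noise.
#' @return A list of class `"thalli_scene"`: `image` (height x width grayscale
#'   matrix, 0-255), `truth` (data.frame: shape, perimeter, area, convex_area,
#'   solidity — continuous-polygon values) and `label` (integer matrix, pixel
#'   to shape index, 0 = background).
#' @export
generate_thalli_image <- function(shapes, canvas_px = c(400, 400),
                                  foreground = 220, background = 10,
                                  intensity_sd = 0, seed = NULL) {
  stopifnot(is.list(shapes), length(canvas_px) == 2L)
  w <- as.integer(canvas_px[1L]); h <- as.integer(canvas_px[2L])
  label <- matrix(0L, h, w)
  if (length(shapes)) {
    cx <- rep(seq_len(w) - 0.5, each = h)   # pixel-center x, column-major
    cy <- rep(seq_len(h) - 0.5, times = w)  # pixel-center y (downwards)
    for (i in seq_along(shapes)) {
      p <- shapes[[i]]
      stopifnot(is.matrix(p), ncol(p) == 2L, nrow(p) >= 3L)
      bb <- which(cx >= min(p[, 1L]) - 1 & cx <= max(p[, 1L]) + 1 &
                  cy >= min(p[, 2L]) - 1 & cy <= max(p[, 2L]) + 1)
      inside <- bb[pracma::inpolygon(cx[bb], cy[bb], p[, 1L], p[, 2L],
                                     boundary = TRUE)]
      if (any(label[inside] != 0L))
        stop("shapes overlap at raster level; per-object truth would be ",
             "ambiguous", call. = FALSE)
      label[inside] <- i
    }
  }
  truth <- if (length(shapes)) {
    cbind(shape = seq_along(shapes),
          do.call(rbind, lapply(shapes, polygon_truth)))
  } else {
    data.frame(shape = integer(), perimeter = numeric(), area = numeric(),
               convex_area = numeric(), solidity = numeric())
  }
  img <- with_seed(seed, {
    base <- ifelse(label > 0L, foreground, background)
    if (intensity_sd > 0) base <- base + rnorm(h * w, 0, intensity_sd)
    matrix(pmin(255, pmax(0, round(base))), h, w)
  })
  structure(list(image = img, truth = truth, label = label),
            class = "thalli_scene")
}
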