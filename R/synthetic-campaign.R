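#' Specify a synthetic sampling campaign along a dredging gradient
#'
#' Bundles everything the campaign generator needs: the station pressures, the
#' per-metric response curves tying each metric's expectation to pressure, and
#' the per-image (or per-thallus) noise around those expectations. Defaults
#' emulate the study conditions: 30 stations of 15 SPI frames along a gradient
#' from 0 to 3.26 times-fully-dredged, in three clusters (0-0.06, 0.61-1.56,
#' 2.52-3.26), with a live/dead ratio decaying exponentially with pressure,
#' penetration decreasing linearly, rugosity decaying exponentially, and
#' thallus perimeter (decreasing) / solidity (increasing) linear in pressure.
#'
#' @param n_stations number of SPI stations (default 30).
#' @param images_per_station SPI frames per station (default 15; at least 2 so
#'   station SDs are defined).
#' @param pressure_values per-station pressure (times fully dredged); default
#'   three even clusters spanning the observed group ranges.
#' @param response named list of response-curve parameters:
#'   `ratio`, `rugosity`, `interstice` as `c(a, b, c)` of `a*exp(-b*p) + c`;
#'   `penetration`, `perimeter`, `solidity` as `c(intercept, slope)`.
#' @param noise_sd named list of per-image (per-thallus) noise scales. All
#'   metrics take additive Gaussian noise truncated to their admissible range,
#'   except `ratio`: the live/dead ratio is strictly positive and
#'   right-skewed, so its noise is multiplicative lognormal and
#'   `noise_sd$ratio` is the log-scale SD (a value of 0.35 spreads a control
#'   station's ratios by roughly +/-40%, matching the wide spread of control
#'   stations, without biasing the fitted decay rate).
#' @param thalli_stations how many stations get thallus cores (default 8,
#'   spread across the gradient).
#' @param cores_per_station,thalli_per_core core sampling intensity.
#' @param seed root seed; all campaign randomness derives from it.
#' @return Object of class `"gradient_spec"`.
#' @export
gradient_spec <- function(n_stations = 30, images_per_station = 15,
                          pressure_values = NULL,
                          response = list(
                            ratio = c(a = 50, b = 1.3, c = 0.5),
                            penetration = c(intercept = 16, slope = -2),
                            rugosity = c(a = 3, b = 1.2, c = 0.5),
                            interstice = c(a = 0.25, b = 0.8, c = 0.05),
                            perimeter = c(intercept = 600, slope = -80),
                            solidity = c(intercept = 0.60, slope = 0.07)),
                          noise_sd = list(ratio = 0.35, penetration = 1.2,
                                          rugosity = 0.35, interstice = 0.02,
                                          perimeter = 40, solidity = 0.03),
                          thalli_stations = 8, cores_per_station = 8,
                          thalli_per_core = 4, seed = 1L) {
  if (is.null(pressure_values)) {
    per <- c(ceiling(n_stations / 3), ceiling((n_stations * 2) / 3) -
               ceiling(n_stations / 3))
    per <- c(per, n_stations - sum(per))
    pressure_values <- c(seq(0, 0.06, length.out = max(per[1L], 1L)),
                         seq(0.61, 1.56, length.out = max(per[2L], 1L)),
                         seq(2.52, 3.26, length.out = max(per[3L], 1L)))
    pressure_values <- pressure_values[seq_len(n_stations)]
  }
  stopifnot(length(pressure_values) == n_stations, all(pressure_values >= 0),
            images_per_station >= 2L)
  for (nm in c("ratio", "penetration", "rugosity", "interstice", "perimeter",
               "solidity")) {
    if (is.null(response[[nm]]) || is.null(noise_sd[[nm]]))
      stop("response and noise_sd must cover metric '", nm, "'", call. = FALSE)
  }
  structure(list(n_stations = n_stations,
                 images_per_station = images_per_station,
                 pressure_values = as.numeric(pressure_values),
                 response = response, noise_sd = noise_sd,
                 thalli_stations = thalli_stations,
                 cores_per_station = cores_per_station,
                 thalli_per_core = thalli_per_core,
                 seed = as.integer(seed)),
            class = "gradient_spec")
}

decay_mean <- function(par, p) par[["a"]] * exp(-par[["b"]] * p) + par[["c"]]
linear_mean <- function(par, p) par[["intercept"]] + par[["slope"]] * p

#' Generate a full synthetic campaign
#'
#' Produces every input stream the analysis pipeline consumes, with ground
#' truth retained: a station table on a 50 m cell lattice, per-station AIS
#' effort whose rasterized pressure reproduces the prescribed station
#' pressures exactly, per-image SPI metric truths drawn around the
#' response curves, per-thallus shape truths, and (optionally) rendered SPI
#' and thalli images written to `dir` as PNG + CSV.
#'
#' @param spec a [gradient_spec()].
#' @param color_model a [color_model()] for rendered SPI images.
#' @param dir if non-NULL, render all images and write the full file set
#'   (PNG images, trace CSVs, station table, ping table, thalli images)
#'   under this directory.
#' @param width_px,height_px,scale_cm_per_px geometry of rendered SPI frames.
#'   The default 725 x 1090 at 0.02 cm/px preserves the 14.5 x 21.8 cm field
#'   (a 5 mm bin is exactly 25 rows); smaller frames keep the same physical
#'   field with coarser pixels.
#' @param n_seasons number of fishing seasons effort is spread over.
#' @param with_tracks generate the AIS effort stream (default TRUE); studies
#'   that only need the image/thalli truths can skip it.
#' @return Object of class `"campaign"`: `stations` (station, pressure, group,
#'   grid row/col), `grid`, `tracks` (an `"ais_tracks"` object),
#'   `image_truth` (per-image metric truths: station, image, ratio,
#'   penetration_cm, rugosity, interstice), `thalli_truth` (per-thallus
#'   analytic truths), `spec`, and when `dir` is given, `paths` to all written
#'   files.
#' @export
generate_campaign <- function(spec = gradient_spec(),
                              color_model = maerlspi::color_model(),
                              dir = NULL,
                              width_px = 725, height_px = 1090,
                              scale_cm_per_px = 0.02,
                              n_seasons = 5, with_tracks = TRUE) {
  stopifnot(inherits(spec, "gradient_spec"))
  seasons <- sprintf("%d-%d", 2012:(2011 + n_seasons), 2013:(2012 + n_seasons))
  n <- spec$n_stations
  n_cols <- ceiling(sqrt(n)); n_rows <- ceiling(n / n_cols)
  grid <- define_grid(c(0, 0), 50, n_rows, n_cols)
  cell_row <- ((seq_len(n) - 1L) %/% n_cols) + 1L
  cell_col <- ((seq_len(n) - 1L) %% n_cols) + 1L
  stations <- data.frame(
    station = sprintf("S%02d", seq_len(n)),
    pressure = spec$pressure_values,
    group = assign_groups(spec$pressure_values),
    row = cell_row, col = cell_col,
    x = (cell_col - 0.5) * 50, y = (cell_row - 0.5) * 50)

  tracks <- if (with_tracks)
    with_seed(derive_seed(spec$seed, 11L),
              campaign_tracks(stations, grid, seasons)) else NULL
  image_truth <- with_seed(derive_seed(spec$seed, 22L),
                           campaign_image_truth(spec, stations, height_px,
                                                scale_cm_per_px))
  thalli_truth <- with_seed(derive_seed(spec$seed, 33L),
                            campaign_thalli_truth(spec, stations))

  out <- structure(list(stations = stations, grid = grid, tracks = tracks,
                        image_truth = image_truth,
                        thalli_truth = thalli_truth, spec = spec,
                        color_model = color_model,
                        geometry = list(width_px = width_px,
                                        height_px = height_px,
                                        scale_cm_per_px = scale_cm_per_px)),
                   class = "campaign")
  if (!is.null(dir)) out$paths <- write_campaign(out, dir)
  out
}

# In-cell dredging passes whose cumulated swept area reproduces each
# station's pressure exactly, plus out-of-window decoy transits.
campaign_tracks <- function(stations, grid, seasons) {
  passes <- list()
  pid <- 0L
  for (i in seq_len(nrow(stations))) {
    target_len <- stations$pressure[i] * grid$cell_size^2 / 1.5
    x0 <- (stations$col[i] - 1) * grid$cell_size
    y0 <- (stations$row[i] - 1) * grid$cell_size
    usable <- grid$cell_size - 4  # 2 m margin keeps passes inside the cell
    remaining <- target_len
    k <- 0L
    while (remaining > 1e-9) {
      len <- min(usable, remaining)
      yy <- y0 + 2 + (k %% 23) * (usable / 23) + runif(1, 0, usable / 46)
      pid <- pid + 1L
      passes[[pid]] <- make_pass(pid, "V1", seasons[(k %% length(seasons)) + 1L],
                                 speed_kn = runif(1, 2.8, 4.5),
                                 from = c(x0 + 2, yy),
                                 to = c(x0 + 2 + len, yy))
      remaining <- remaining - len
      k <- k + 1L
    }
  }
  # a decoy transit pass above the speed window (contributes nothing)
  pid <- pid + 1L
  passes[[pid]] <- make_pass(pid, "V1", seasons[1L], speed_kn = 7.5,
                             from = c(2, 2),
                             to = c(grid$n_cols * grid$cell_size - 2, 2))
  generate_ais_tracks(do.call(rbind, passes), grid)
}

truncnorm1 <- function(mean, sd, lo, hi) min(hi, max(lo, mean + rnorm(1, 0, sd)))

# Per-image target metrics: expectation from the response curves + Gaussian
# noise, truncated to physically admissible ranges.
campaign_image_truth <- function(spec, stations, height_px, scale_cm_per_px) {
  max_pen <- height_px * scale_cm_per_px - 1
  rows <- list()
  for (i in seq_len(nrow(stations))) {
    p <- stations$pressure[i]
    for (j in seq_len(spec$images_per_station)) {
      rows[[length(rows) + 1L]] <- data.frame(
        station = stations$station[i], image = sprintf("img%02d", j),
        ratio = min(400, max(0.02, decay_mean(spec$response$ratio, p) *
                               exp(rnorm(1, 0, spec$noise_sd$ratio)))),
        penetration_cm = truncnorm1(linear_mean(spec$response$penetration, p),
                                    spec$noise_sd$penetration, 2, max_pen),
        rugosity = truncnorm1(decay_mean(spec$response$rugosity, p),
                              spec$noise_sd$rugosity, 0.02, 30),
        interstice = truncnorm1(decay_mean(spec$response$interstice, p),
                                spec$noise_sd$interstice, 0.01, 0.6))
    }
  }
  do.call(rbind, rows)
}

# Per-thallus truths: 6-spiked stars whose inner/outer radius ratio is set
# from the target solidity (solidity = (r/R) / cos(pi/n) for such stars) and
# whose size is scaled to the target perimeter.
campaign_thalli_truth <- function(spec, stations) {
  sel <- unique(round(seq(1, nrow(stations),
                          length.out = min(spec$thalli_stations,
                                           nrow(stations)))))
  n_spikes <- 6L
  rows <- list()
  for (i in sel) {
    p <- stations$pressure[i]
    for (core in seq_len(spec$cores_per_station)) {
      for (t in seq_len(spec$thalli_per_core)) {
        sol <- truncnorm1(linear_mean(spec$response$solidity, p),
                          spec$noise_sd$solidity, 0.35, 0.84)
        per <- truncnorm1(linear_mean(spec$response$perimeter, p),
                          spec$noise_sd$perimeter, 120, 1500)
        rho <- sol * cos(pi / n_spikes)
        # unit-R star perimeter, then scale R to hit the target perimeter
        unit <- poly_star(n_spikes, 1, rho)
        R <- per / polygon_perimeter(unit)
        tru <- polygon_truth(poly_star(n_spikes, R, rho * R))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(station = stations$station[i], pressure = p,
                     core = sprintf("C%02d", core), thallus = t,
                     R = R, rho = rho), tru)
      }
    }
  }
  do.call(rbind, rows)
}

#' Render one campaign SPI scene
#'
#' Realizes the SPI image + trace for one row of a campaign's `image_truth`:
#' a reflected-random-walk interface scaled to the target rugosity and
#' centred on the target penetration depth, and a constant-with-depth
#' composition whose live/dead split matches the target ratio and interstice
#' fraction. Rounding the trace to integer rows makes achieved metrics differ
#' slightly from the targets; the returned scene truth holds the achieved
#' values.
#'
#' @param campaign a `"campaign"` object.
#' @param station,image identifiers of the frame to render.
#' @param seed integer seed (default derived from the campaign seed and the
#'   frame index).
#' @return An `"spi_scene"` (see [generate_spi_image()]).
#' @export
render_campaign_image <- function(campaign, station, image, seed = NULL) {
  it <- campaign$image_truth
  k <- which(it$station == station & it$image == image)
  if (length(k) != 1L) stop("unknown station/image", call. = FALSE)
  g <- campaign$geometry
  tr <- it[k, ]
  if (is.null(seed)) seed <- derive_seed(campaign$spec$seed, 1000L + k)
  base_row <- g$height_px - tr$penetration_cm / g$scale_cm_per_px
  band <- max(4, min(40 / 0.02 * g$scale_cm_per_px, base_row - 1,
                     g$height_px - 2 - base_row))
  live <- (1 - tr$interstice) * tr$ratio / (1 + tr$ratio)
  dead <- (1 - tr$interstice) / (1 + tr$ratio)
  generate_spi_image(
    width_px = g$width_px, height_px = g$height_px,
    scale_cm_per_px = g$scale_cm_per_px,
    interface = interface_walk(base_row,
                               step_sd = tr$rugosity * 1.2533, # E|N(0,s)| = s*sqrt(2/pi)
                               band = band),
    composition = c(live = live, dead = dead, interstice = tr$interstice),
    color_model = campaign$color_model, seed = seed)
}

#' Render one campaign thalli core image
#'
#' Rasterizes the star polygons of one core onto a black canvas, laid out on a
#' collision-free grid.
#'
#' @inheritParams render_campaign_image
#' @param core core identifier.
#' @return A `"thalli_scene"` (see [generate_thalli_image()]).
#' @export
render_campaign_core <- function(campaign, station, core, seed = NULL) {
  tt <- campaign$thalli_truth
  d <- tt[tt$station == station & tt$core == core, , drop = FALSE]
  if (!nrow(d)) stop("unknown station/core", call. = FALSE)
  rad <- d$R
  pitch <- 2 * max(rad) + 12
  n_side <- ceiling(sqrt(nrow(d)))
  shapes <- lapply(seq_len(nrow(d)), function(i) {
    cx <- ((i - 1L) %% n_side + 0.5) * pitch
    cy <- ((i - 1L) %/% n_side + 0.5) * pitch
    poly_star(6L, d$R[i], d$rho[i] * d$R[i], center = c(cx, cy))
  })
  canvas <- rep(ceiling(n_side * pitch) + 2, 2L)
  if (is.null(seed))
    seed <- derive_seed(campaign$spec$seed,
                        2000L + which(tt$station == station &
                                      tt$core == core)[1L])
  generate_thalli_image(shapes, canvas_px = canvas, intensity_sd = 6,
                        seed = seed)
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf(
    "synthetic campaign: %d stations x %d SPI frames (pressure %.3g-%.3g)\n",
    nrow(x$stations), x$spec$images_per_station,
    min(x$stations$pressure), max(x$stations$pressure)))
  cat(sprintf("  %d AIS pings, %d thallus truths, seed %d\n",
              if (is.null(x$tracks)) 0L else nrow(x$tracks$pings),
              nrow(x$thalli_truth), x$spec$seed))
  invisible(x)
}
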