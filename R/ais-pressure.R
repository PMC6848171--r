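#' Define the pressure-grid lattice
#'
#' The dredging-intensity raster lives on a lattice of square cells (default
#' 50 m, i.e. 2500 m2 per cell). Cells are half-open:
#' `[x0 + (i-1)*cs, x0 + i*cs) x [y0 + (j-1)*cs, y0 + j*cs)`, so a point on a
#' shared edge belongs to the higher-index cell. The origin must be supplied:
#' geographic registration is a property of the study, not of the method.
#'
#' @param origin `c(x0, y0)` lower-left corner in projected metres.
#' @param cell_size cell edge in metres (default 50).
#' @param n_rows,n_cols lattice extent (rows run along y, columns along x).
#' @return An object of class `"dredge_grid"`.
#' @export
define_grid <- function(origin = c(0, 0), cell_size = 50, n_rows, n_cols) {
  stop_if_not_scalar(cell_size, "cell_size", lo = 1e-9)
  stopifnot(length(origin) == 2L, n_rows >= 1L, n_cols >= 1L)
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "dredge_grid")
}

#' @export
print.dredge_grid <- function(x, ...) {
  cat(sprintf("dredge grid: %d x %d cells of %g m (origin %g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1L], x$origin[2L]))
  invisible(x)
}

#' Detect dredging segments from AIS pings
#'
#' A vessel is considered to be actively dredging when its speed over ground
#' falls inside the fleet's typical fishing window (default 2.5-5 knots).
#' Maximal runs of at least two consecutive in-window pings of an in-fleet
#' vessel, within one season, become one dredging segment whose polyline joins
#' the ping positions with straight chords. Out-of-window or out-of-fleet
#' pings, and season or vessel changes, break runs; an isolated in-window ping
#' yields no segment.
#'
#' @param pings data.frame with columns `vessel_id`, `timestamp` (seconds,
#'   strictly increasing per vessel), `x`, `y` (projected metres), `speed`
#'   (knots, non-negative) and `season`; an optional logical `in_fleet`
#'   (default all TRUE).
#' @param speed_window `c(lower, upper)` dredging speed window in knots
#'   (inclusive).
#' @return A data.frame of class `"dredge_segments"` with one row per segment
#'   vertex: `segment_id`, `vessel_id`, `season`, `x`, `y`. Use
#'   [segment_lengths()] for per-segment polyline lengths.
#' @export
detect_dredging_segments <- function(pings, speed_window = c(2.5, 5.0)) {
  need <- c("vessel_id", "timestamp", "x", "y", "speed", "season")
  if (!all(need %in% names(pings)))
    stop("pings must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(pings$in_fleet)) pings$in_fleet <- TRUE
  if (any(pings$speed < 0)) stop("negative speeds in ping table", call. = FALSE)
  for (v in unique(pings$vessel_id)) {
    ts <- pings$timestamp[pings$vessel_id == v]
    if (is.unsorted(ts, strictly = TRUE))
      stop("pings not strictly ordered in time for vessel '", v,
           "': sort per vessel by timestamp first", call. = FALSE)
  }
  ok <- pings$in_fleet & pings$speed >= speed_window[1L] &
    pings$speed <= speed_window[2L]
  key <- paste(pings$vessel_id, pings$season, sep = "\r")
  # run starts where ok begins or the vessel/season key changes
  n <- nrow(pings)
  newblock <- c(TRUE, key[-1L] != key[-n] | !ok[-1L] | !ok[-n])
  run_id <- cumsum(newblock)
  keep <- ok
  run_id[!keep] <- NA
  sizes <- table(run_id)
  good <- as.integer(names(sizes)[sizes >= 2L])
  rows <- which(!is.na(run_id) & run_id %in% good)
  if (!length(rows)) {
    out <- data.frame(segment_id = integer(), vessel_id = character(),
                      season = character(), x = numeric(), y = numeric())
  } else {
    seg <- match(run_id[rows], good)
    out <- data.frame(segment_id = seg,
                      vessel_id = pings$vessel_id[rows],
                      season = pings$season[rows],
                      x = pings$x[rows], y = pings$y[rows])
  }
  class(out) <- c("dredge_segments", class(out))
  out
}

#' Per-segment polyline lengths
#'
#' @param segments a `"dredge_segments"` data.frame.
#' @return data.frame: `segment_id`, `vessel_id`, `season`, `length_m`.
#' @export
segment_lengths <- function(segments) {
  sp <- split(seq_len(nrow(segments)), segments$segment_id)
  out <- do.call(rbind, lapply(sp, function(i) {
    d <- segments[i, ]
    data.frame(segment_id = d$segment_id[1L], vessel_id = d$vessel_id[1L],
               season = d$season[1L],
               length_m = sum(sqrt(diff(d$x)^2 + diff(d$y)^2)))
  }))
  rownames(out) <- NULL
  out
}

# Clip one chord (x0,y0)-(x1,y1) against the cell lattice. Returns a
# data.frame(row, col, length). Pieces outside the grid extent raise an error
# unless clip = TRUE (then they are dropped).
clip_chord_to_grid <- function(x0, y0, x1, y1, grid, clip = FALSE) {
  L <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (L == 0) return(data.frame(row = integer(), col = integer(),
                                length = numeric()))
  cs <- grid$cell_size; ox <- grid$origin[1L]; oy <- grid$origin[2L]
  tx <- ty <- numeric()
  if (x1 != x0) {
    lo <- ceiling((min(x0, x1) - ox) / cs); hi <- floor((max(x0, x1) - ox) / cs)
    if (hi >= lo) tx <- ((ox + (lo:hi) * cs) - x0) / (x1 - x0)
  }
  if (y1 != y0) {
    lo <- ceiling((min(y0, y1) - oy) / cs); hi <- floor((max(y0, y1) - oy) / cs)
    if (hi >= lo) ty <- ((oy + (lo:hi) * cs) - y0) / (y1 - y0)
  }
  t <- sort(unique(c(0, 1, tx[tx > 0 & tx < 1], ty[ty > 0 & ty < 1])))
  tm <- (t[-length(t)] + t[-1L]) / 2
  xm <- x0 + tm * (x1 - x0); ym <- y0 + tm * (y1 - y0)
  col <- floor((xm - ox) / cs) + 1L
  row <- floor((ym - oy) / cs) + 1L
  len <- L * diff(t)
  inside <- col >= 1L & col <= grid$n_cols & row >= 1L & row <= grid$n_rows
  if (any(!inside) && !clip)
    stop("segment extends outside the grid; enlarge the grid or set ",
         "clip = TRUE to drop outside pieces explicitly", call. = FALSE)
  data.frame(row = row[inside], col = col[inside], length = len[inside])
}

#' Rasterize swept area of dredging segments onto the grid
#'
#' Each polyline chord is clipped against the cell lattice; the swept area
#' credited to a cell is the clipped length inside that cell multiplied by the
#' dredge width. Total allocated area equals segment length times width
#' (conservation), up to floating-point clipping tolerance, unless pieces are
#' explicitly clipped away at the grid boundary.
#'
#' @param segments a `"dredge_segments"` data.frame (or any data.frame with
#'   `segment_id`, `season`, `x`, `y` vertex rows).
#' @param grid a [define_grid()] lattice.
#' @param dredge_width_m gear width in metres (default 1.5, a single clam
#'   dredge).
#' @param clip drop polyline pieces outside the grid instead of erroring.
#' @return data.frame: `season`, `row`, `col`, `swept_m2`, aggregated over
#'   segments.
#' @export
rasterize_swept_area <- function(segments, grid, dredge_width_m = 1.5,
                                 clip = FALSE) {
  stopifnot(inherits(grid, "dredge_grid"))
  stop_if_not_scalar(dredge_width_m, "dredge_width_m", lo = 1e-9)
  pieces <- list()
  for (sid in unique(segments$segment_id)) {
    d <- segments[segments$segment_id == sid, ]
    for (i in seq_len(nrow(d) - 1L)) {
      p <- clip_chord_to_grid(d$x[i], d$y[i], d$x[i + 1L], d$y[i + 1L],
                              grid, clip = clip)
      if (nrow(p)) {
        p$season <- d$season[1L]
        pieces[[length(pieces) + 1L]] <- p
      }
    }
  }
  if (!length(pieces))
    return(data.frame(season = character(), row = integer(), col = integer(),
                      swept_m2 = numeric()))
  all <- do.call(rbind, pieces)
  agg <- aggregate(list(swept_m2 = all$length * dredge_width_m),
                   by = list(season = all$season, row = all$row, col = all$col),
                   FUN = sum)
  agg[order(agg$season, agg$row, agg$col), , drop = FALSE]
}

#' Cumulate swept areas into a dredging-pressure raster
#'
#' Sums per-season swept areas over the requested seasons and divides by the
#' cell area, expressing pressure as the number of times each cell has been
#' fully dredged over the season set. Values above 1 mean repeated full
#' coverage. A requested season absent from the data contributes a zero layer
#' with a warning.
#'
#' @param swept data.frame from [rasterize_swept_area()].
#' @param grid a [define_grid()] lattice.
#' @param seasons character vector of seasons to cumulate; default all seasons
#'   present.
#' @return An object of class `"pressure_grid"`: the `grid`, the `seasons`,
#'   the per-season `swept` table and the `pressure` matrix
#'   (`n_rows x n_cols`).
#' @export
cumulate_pressure <- function(swept, grid, seasons = NULL) {
  stopifnot(inherits(grid, "dredge_grid"))
  if (is.null(seasons)) seasons <- sort(unique(as.character(swept$season)))
  missing <- setdiff(seasons, unique(as.character(swept$season)))
  if (length(missing))
    warning("no swept area recorded for season(s): ",
            paste(missing, collapse = ", "), "; treated as zero layers",
            call. = FALSE)
  press <- matrix(0, grid$n_rows, grid$n_cols)
  use <- swept[as.character(swept$season) %in% seasons, , drop = FALSE]
  if (nrow(use)) {
    idx <- cbind(use$row, use$col)
    for (k in seq_len(nrow(use)))
      press[idx[k, 1L], idx[k, 2L]] <- press[idx[k, 1L], idx[k, 2L]] +
        use$swept_m2[k]
  }
  press <- press / grid$cell_size^2
  structure(list(grid = grid, seasons = seasons, swept = use,
                 pressure = press),
            class = "pressure_grid")
}

#' @export
print.pressure_grid <- function(x, ...) {
  cat(sprintf(
    "dredging pressure over %d season(s) on a %d x %d grid of %g m cells\n",
    length(x$seasons), x$grid$n_rows, x$grid$n_cols, x$grid$cell_size))
  cat(sprintf("  pressure (times fully dredged): range %.3g - %.3g\n",
              min(x$pressure), max(x$pressure)))
  invisible(x)
}

#' @export
as.data.frame.pressure_grid <- function(x, ...) {
  g <- x$grid
  idx <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  data.frame(idx,
             x_center = g$origin[1L] + (idx$col - 0.5) * g$cell_size,
             y_center = g$origin[2L] + (idx$row - 0.5) * g$cell_size,
             pressure = x$pressure[cbind(idx$row, idx$col)])
}

#' Assign dredging-pressure groups
#'
#' Discretizes pressure values into the three study groups: `Control`
#' (pressure <= first threshold), `Moderate` (between the thresholds) and
#' `High` (above the second). Default thresholds 0.1 and 2.0 sit inside the
#' gaps between the observed group ranges (0-0.06, 0.61-1.56, 2.52-3.26).
#'
#' @param pressure numeric vector of non-negative pressures (times fully
#'   dredged).
#' @param thresholds strictly increasing `c(t1, t2)`.
#' @return factor with levels `Control`, `Moderate`, `High`.
#' @export
assign_groups <- function(pressure, thresholds = c(0.1, 2.0)) {
  stopifnot(length(thresholds) == 2L, thresholds[1L] < thresholds[2L])
  if (any(pressure < 0)) stop("negative pressure values", call. = FALSE)
  cut(pressure, breaks = c(-Inf, thresholds, Inf),
      labels = c("Control", "Moderate", "High"), right = TRUE)
}
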