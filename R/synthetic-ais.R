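#' Generate synthetic AIS ping tracks with exact swept-area truth
#'
#' Emits AIS pings along planned passes (straight or polyline) at a fixed time
#' interval, and records, per grid cell and season, the exact swept area
#' contributed by passes inside the dredging speed window (polyline length
#' within the cell, clipped analytically, times the dredge width). A ping is
#' placed exactly at each pass endpoint in addition to the interval pings, so
#' the ping-chord polyline spans the full pass and the analytic truth is
#' attainable by the recovery pipeline.
#'
#' @param passes data.frame of ordered pass vertices: columns `pass_id`,
#'   `vessel_id`, `season`, `speed_kn`, `x`, `y`, and optionally `in_fleet`
#'   (default TRUE). Several rows with the same `pass_id` form a polyline.
#' @param grid a [define_grid()] lattice for the truth.
#' @param ping_interval_s ping interval in seconds (> 0).
#' @param speed_window dredging speed window in knots used for the truth.
#' @param dredge_width_m gear width in metres for the truth.
#' @param start_time epoch of the first ping (seconds); passes of the same
#'   vessel are separated by an idle gap so timestamps stay strictly
#'   increasing.
#' @param clip passed to the analytic clipping of the truth.
#' @return A list of class `"ais_tracks"`: `pings` (data.frame `vessel_id`,
#'   `timestamp`, `x`, `y`, `speed`, `season`, `in_fleet`) and `truth`
#'   (data.frame `season`, `row`, `col`, `swept_m2`, only in-window in-fleet
#'   passes).
#' @export
generate_ais_tracks <- function(passes, grid, ping_interval_s = 10,
                                speed_window = c(2.5, 5.0),
                                dredge_width_m = 1.5, start_time = 0,
                                clip = FALSE) {
  stop_if_not_scalar(ping_interval_s, "ping_interval_s", lo = 1e-9)
  need <- c("pass_id", "vessel_id", "season", "speed_kn", "x", "y")
  if (!all(need %in% names(passes)))
    stop("passes must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(passes$in_fleet)) passes$in_fleet <- TRUE

  ping_rows <- list()
  truth_pieces <- list()
  t_next <- setNames(rep(start_time, length(unique(passes$vessel_id))),
                     unique(passes$vessel_id))
  for (pid in unique(passes$pass_id)) {
    d <- passes[passes$pass_id == pid, ]
    v_ms <- d$speed_kn[1L] * 0.514444
    seg_len <- sqrt(diff(d$x)^2 + diff(d$y)^2)
    L <- sum(seg_len)
    if (L <= 0) next
    # pings along cumulative distance; every polyline vertex (and so the
    # endpoint) carries a ping, so ping chords never cut corners
    cum <- c(0, cumsum(seg_len))
    s <- sort(unique(c(seq(0, L, by = v_ms * ping_interval_s), cum)))
    seg_of <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
                   length(seg_len))
    frac <- (s - cum[seg_of]) / seg_len[seg_of]
    px <- d$x[seg_of] + frac * (d$x[seg_of + 1L] - d$x[seg_of])
    py <- d$y[seg_of] + frac * (d$y[seg_of + 1L] - d$y[seg_of])
    vkey <- as.character(d$vessel_id[1L])
    t0 <- t_next[[vkey]]
    if (t0 > start_time) {
      # transit ping between passes (above the speed window) so the
      # maximal-run rule never bridges two distinct passes into one segment
      ping_rows[[length(ping_rows) + 1L]] <- data.frame(
        vessel_id = d$vessel_id[1L], timestamp = t0 - 300,
        x = d$x[1L], y = d$y[1L], speed = 8, season = d$season[1L],
        in_fleet = d$in_fleet[1L])
    }
    ping_rows[[length(ping_rows) + 1L]] <- data.frame(
      vessel_id = d$vessel_id[1L], timestamp = t0 + s / v_ms,
      x = px, y = py, speed = d$speed_kn[1L], season = d$season[1L],
      in_fleet = d$in_fleet[1L])
    t_next[[vkey]] <- t0 + L / v_ms + 600

    in_window <- d$speed_kn[1L] >= speed_window[1L] &&
      d$speed_kn[1L] <= speed_window[2L] && isTRUE(d$in_fleet[1L])
    if (in_window) {
      for (i in seq_len(nrow(d) - 1L)) {
        p <- clip_chord_to_grid(d$x[i], d$y[i], d$x[i + 1L], d$y[i + 1L],
                                grid, clip = clip)
        if (nrow(p)) {
          p$season <- d$season[1L]
          truth_pieces[[length(truth_pieces) + 1L]] <- p
        }
      }
    }
  }
  pings <- if (length(ping_rows)) do.call(rbind, ping_rows) else
    data.frame(vessel_id = character(), timestamp = numeric(), x = numeric(),
               y = numeric(), speed = numeric(), season = character(),
               in_fleet = logical())
  pings <- pings[order(pings$vessel_id, pings$timestamp), , drop = FALSE]
  rownames(pings) <- NULL
  truth <- if (length(truth_pieces)) {
    all <- do.call(rbind, truth_pieces)
    agg <- aggregate(list(swept_m2 = all$length * dredge_width_m),
                     by = list(season = all$season, row = all$row,
                               col = all$col), FUN = sum)
    agg[order(agg$season, agg$row, agg$col), , drop = FALSE]
  } else {
    data.frame(season = character(), row = integer(), col = integer(),
               swept_m2 = numeric())
  }
  structure(list(pings = pings, truth = truth, grid = grid),
            class = "ais_tracks")
}

#' Build a straight pass for an effort plan
#'
#' Convenience constructor for one row-block of the `passes` table consumed by
#' [generate_ais_tracks()].
#'
#' @param pass_id,vessel_id,season identifiers.
#' @param speed_kn speed over ground in knots.
#' @param from,to `c(x, y)` endpoints in metres.
#' @param in_fleet whether the vessel belongs to the dredging fleet.
#' @return A two-row data.frame of pass vertices.
#' @export
make_pass <- function(pass_id, vessel_id, season, speed_kn, from, to,
                      in_fleet = TRUE) {
  data.frame(pass_id = pass_id, vessel_id = vessel_id, season = season,
             speed_kn = speed_kn, x = c(from[1L], to[1L]),
             y = c(from[2L], to[2L]), in_fleet = in_fleet)
}
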