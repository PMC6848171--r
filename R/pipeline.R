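#' Configure an end-to-end pipeline run
#'
#' Collects paths, thresholds and sizes for [run_pipeline()]. Either point the
#' config at existing inputs (ping CSV, SPI image + trace directories, thalli
#' images, station table) or pass a [gradient_spec()] as `simulate` to let the
#' run generate its own campaign under `out_dir/inputs` first.
#'
#' @param out_dir output directory (created if missing).
#' @param pings,spi_dir,traces_dir,thalli_dir,thalli_map,stations input paths;
#'   ignored when `simulate` is given.
#' @param simulate optional [gradient_spec()] for a self-generated campaign.
#' @param sim_geometry list(width_px, height_px, scale_cm_per_px) for the
#'   simulated SPI frames.
#' @param scale_cm_per_px pixel size of the SPI images.
#' @param red_threshold,dark_threshold classification thresholds.
#' @param group_thresholds pressure-group cut points.
#' @param grid_origin,cell_size,n_rows,n_cols pressure-grid lattice; when NULL
#'   the lattice is sized from the ping extent.
#' @param bin_cm,max_depth_cm profile binning.
#' @param n_permutations permutations for the statistical tests.
#' @param seed root seed; every stage derives its own stream from it.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            pings = NULL, spi_dir = NULL, traces_dir = NULL,
                            thalli_dir = NULL, thalli_map = NULL,
                            stations = NULL,
                            simulate = NULL,
                            sim_geometry = list(width_px = 181,
                                                height_px = 272,
                                                scale_cm_per_px = 0.08),
                            scale_cm_per_px = 0.02,
                            red_threshold = 185, dark_threshold = 95,
                            group_thresholds = c(0.1, 2.0),
                            grid_origin = NULL, cell_size = 50,
                            n_rows = NULL, n_cols = NULL,
                            bin_cm = 0.5, max_depth_cm = 10,
                            n_permutations = 999, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full dredging-impact pipeline
#'
#' Orchestrates all stages: (1) AIS pings to a cumulated dredging-pressure
#' raster; (2) SPI images + traces to per-image metrics and 5 mm vertical
#' profiles; (3) thalli silhouettes to shape descriptors; (4) station-scale
#' aggregation; (5) PERMANOVA / PERMDISP group tests on station averages and
#' SDs (univariate metrics and normalized 0-10 cm multivariate profiles) plus
#' pressure-response model selection. Every stage writes its CSV outputs under
#' `out_dir` and a manifest records the config, seed, package version and
#' input checksums. A failing stage aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return A result bundle of class `"maerl_pipeline"` with the pressure
#'   grid, per-image tables, station summary, statistics tables, fitted
#'   curves and file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$simulate)) {
    camp <- stage("simulate", generate_campaign(
      cfg$simulate, dir = file.path(cfg$out_dir, "inputs"),
      width_px = cfg$sim_geometry$width_px,
      height_px = cfg$sim_geometry$height_px,
      scale_cm_per_px = cfg$sim_geometry$scale_cm_per_px))
    cfg$pings <- camp$paths$pings
    cfg$spi_dir <- camp$paths$spi
    cfg$traces_dir <- camp$paths$traces
    cfg$thalli_dir <- camp$paths$thalli
    cfg$thalli_map <- file.path(camp$paths$dir, "thalli_map.csv")
    cfg$stations <- camp$paths$stations
    cfg$scale_cm_per_px <- cfg$sim_geometry$scale_cm_per_px
    cfg$grid_origin <- camp$grid$origin
    cfg$n_rows <- camp$grid$n_rows
    cfg$n_cols <- camp$grid$n_cols
  }

  station_table <- stage("stations", {
    st <- read.csv(cfg$stations)
    stopifnot(all(c("station", "row", "col") %in% names(st)))
    st
  })

  # --- pressure -------------------------------------------------------------
  pressure <- stage("pressure", {
    pings <- read_pings(cfg$pings)
    if (is.null(cfg$grid_origin)) {
      cfg$grid_origin <- floor(c(min(pings$x), min(pings$y)) / cfg$cell_size) *
        cfg$cell_size
    }
    n_rows <- cfg$n_rows %||%
      (floor((max(pings$y) - cfg$grid_origin[2L]) / cfg$cell_size) + 1L)
    n_cols <- cfg$n_cols %||%
      (floor((max(pings$x) - cfg$grid_origin[1L]) / cfg$cell_size) + 1L)
    grid <- define_grid(cfg$grid_origin, cfg$cell_size, n_rows, n_cols)
    segs <- detect_dredging_segments(pings)
    swept <- rasterize_swept_area(segs, grid, clip = TRUE)
    cumulate_pressure(swept, grid)
  })
  write.csv(as.data.frame(pressure), file.path(cfg$out_dir, "pressure_grid.csv"),
            row.names = FALSE)
  write.csv(pressure$swept, file.path(cfg$out_dir, "swept_by_season.csv"),
            row.names = FALSE)
  station_table$pressure_measured <-
    pressure$pressure[cbind(station_table$row, station_table$col)]
  if (is.null(station_table$pressure))
    station_table$pressure <- station_table$pressure_measured
  station_table$group <- assign_groups(station_table$pressure_measured,
                                       cfg$group_thresholds)

  # --- SPI image analysis ---------------------------------------------------
  spi <- stage("spi", {
    imgs <- sort(list.files(cfg$spi_dir, pattern = "\\.(png|tif|tiff)$",
                            ignore.case = TRUE))
    if (!length(imgs)) stop("no SPI images found in ", cfg$spi_dir)
    metrics <- list(); profiles <- list()
    for (f in imgs) {
      stem <- tools::file_path_sans_ext(f)
      parts <- strsplit(stem, "_")[[1L]]
      trace <- read_trace(file.path(cfg$traces_dir, paste0(stem, ".csv")))
      res <- analyze_spi_image(read_image(file.path(cfg$spi_dir, f)), trace,
                               cfg$scale_cm_per_px, cfg$red_threshold,
                               cfg$dark_threshold, cfg$bin_cm,
                               cfg$max_depth_cm)
      res$metrics <- cbind(data.frame(station = parts[1L], image = parts[2L]),
                           res$metrics)
      res$profiles <- cbind(data.frame(station = parts[1L], image = parts[2L]),
                            res$profiles)
      metrics[[stem]] <- res$metrics
      profiles[[stem]] <- res$profiles
    }
    list(metrics = do.call(rbind, metrics), profiles = do.call(rbind, profiles))
  })
  rownames(spi$metrics) <- rownames(spi$profiles) <- NULL
  write.csv(spi$metrics, file.path(cfg$out_dir, "image_metrics.csv"),
            row.names = FALSE)
  write.csv(spi$profiles, file.path(cfg$out_dir, "image_profiles.csv"),
            row.names = FALSE)

  # --- thalli ---------------------------------------------------------------
  thalli <- stage("thalli", {
    if (is.null(cfg$thalli_dir) || !dir.exists(cfg$thalli_dir) ||
        !length(list.files(cfg$thalli_dir))) return(NULL)
    rows <- list()
    for (f in sort(list.files(cfg$thalli_dir, pattern = "\\.png$"))) {
      stem <- tools::file_path_sans_ext(f)
      parts <- strsplit(stem, "_")[[1L]]
      shapes <- segment_thalli(read_image(file.path(cfg$thalli_dir, f)))
      if (!length(shapes)) next
      meas <- do.call(rbind, lapply(shapes, measure_shape))
      rows[[stem]] <- cbind(data.frame(station = parts[1L], core = parts[2L]),
                            meas)
    }
    if (!length(rows)) return(NULL)
    per_thallus <- do.call(rbind, rows)
    rownames(per_thallus) <- NULL
    names(per_thallus)[names(per_thallus) == "perimeter_px"] <- "perimeter_px"
    list(per_thallus = per_thallus,
         station = station_morphology(per_thallus))
  })
  if (!is.null(thalli)) {
    write.csv(thalli$per_thallus, file.path(cfg$out_dir, "thalli.csv"),
              row.names = FALSE)
    write.csv(thalli$station, file.path(cfg$out_dir, "thalli_stations.csv"),
              row.names = FALSE)
  }

  # --- station aggregation --------------------------------------------------
  summary <- stage("aggregate", {
    st <- station_table
    st$pressure <- st$pressure_measured
    aggregate_stations(spi$metrics, spi$profiles, st,
                       max_depth_cm = cfg$max_depth_cm, bin_cm = cfg$bin_cm)
  })
  write.csv(summary$metrics, file.path(cfg$out_dir, "station_summary.csv"),
            row.names = FALSE)

  # --- statistics -----------------------------------------------------------
  stats_out <- stage("stats", pipeline_stats(summary, cfg))
  write.csv(stats_out$table, file.path(cfg$out_dir, "permanova_table.csv"),
            row.names = FALSE)

  fits <- stage("fits", pipeline_fits(summary, thalli, cfg))
  write.csv(fits$table, file.path(cfg$out_dir, "fits.csv"), row.names = FALSE)

  manifest <- list(
    config = cfg[!vapply(cfg, is.null, TRUE) &
                   !names(cfg) %in% c("simulate", "sim_geometry")],
    simulated = !is.null(config$simulate),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("maerlspi")),
    input_checksums = as.list(tools::md5sum(
      c(cfg$pings, cfg$stations)[file.exists(c(cfg$pings, cfg$stations))])),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(config = cfg, pressure = pressure,
                 image_metrics = spi$metrics, image_profiles = spi$profiles,
                 thalli = thalli, station_summary = summary,
                 stats = stats_out, fits = fits,
                 station_table = station_table, out_dir = cfg$out_dir),
            class = "maerl_pipeline")
}

# Table-1-shaped statistics: per metric x scale, main PERMANOVA, pairwise,
# PERMDISP; multivariate tests on normalized 0-10 cm profile matrices.
pipeline_stats <- function(summary, cfg) {
  met <- summary$metrics
  groups <- met$group
  rows <- list(); details <- list()
  kseed <- 0L
  run_one <- function(variable, scl, y, multivariate = FALSE) {
    kseed <<- kseed + 1L
    ok <- if (is.matrix(y)) complete.cases(y) else is.finite(y)
    g <- droplevels(factor(groups[ok]))
    y <- if (is.matrix(y)) y[ok, , drop = FALSE] else y[ok]
    if (nlevels(g) < 2L || any(table(g) < 2L)) return(NULL)
    if (multivariate) y <- normalize_profiles(y)
    pm <- permanova_oneway(y, g, n_permutations = cfg$n_permutations,
                           seed = derive_seed(cfg$seed, 500L + kseed))
    pd <- permdisp(y, g, n_permutations = cfg$n_permutations,
                   seed = derive_seed(cfg$seed, 700L + kseed), pairwise = TRUE)
    pp <- function(g1, g2, d) {
      r <- d[(d$group1 == g1 & d$group2 == g2) |
               (d$group1 == g2 & d$group2 == g1), ]
      if (nrow(r)) r$p[1L] else NA_real_
    }
    details[[paste(variable, scl)]] <<- list(permanova = pm, permdisp = pd)
    data.frame(variable = variable, scale = scl,
               df = unname(pm$df[1L]), pseudo_F = pm$statistic,
               p_perm = pm$p_value,
               p_control_vs_moderate = pp("Control", "Moderate", pm$pairwise),
               p_control_vs_high = pp("Control", "High", pm$pairwise),
               p_moderate_vs_high = pp("Moderate", "High", pm$pairwise),
               dispersion_F = pd$statistic, dispersion_p = pd$p_value)
  }
  tab <- list(
    run_one("Interface rugosity", "average", met$rugosity_mean),
    run_one("Interface rugosity", "SD", met$rugosity_sd),
    run_one("SPI penetration depth", "average", met$penetration_mean),
    run_one("SPI penetration depth", "SD", met$penetration_sd),
    run_one("Maerl live/dead ratio", "average", met$ratio_mean),
    run_one("Maerl live/dead ratio", "SD", met$ratio_sd))
  for (cls in c("live", "dead", "interstice")) {
    for (scl in c("mean", "sd")) {
      m <- summary$profiles[[scl]][[cls]]
      keep <- apply(m, 2L, function(col) all(is.finite(col)))
      tab[[length(tab) + 1L]] <-
        run_one(sprintf("%s profiles (0-%g cm)",
                        c(live = "Live maerl", dead = "Dead maerl",
                          interstice = "Interstitial space")[[cls]],
                        cfg$max_depth_cm),
                c(mean = "average", sd = "SD")[[scl]],
                m[, keep, drop = FALSE], multivariate = TRUE)
    }
  }
  list(table = do.call(rbind, tab), details = details)
}

# Pressure-response model selection per metric x scale + thalli linear fits.
pipeline_fits <- function(summary, thalli, cfg) {
  met <- summary$metrics
  fits <- list(); rows <- list()
  add <- function(variable, scl, x, y, families) {
    cmp <- tryCatch(
      compare_response_families(x, y, families,
                                seed = derive_seed(cfg$seed, 900L)),
      error = function(e) NULL)
    if (is.null(cmp)) return()
    best <- attr(cmp, "fits")[[cmp$family[1L]]]
    fits[[paste(variable, scl)]] <<- best
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, scale = scl, family = best$family,
      coefficients = paste(sprintf("%s=%.6g", names(best$coefficients),
                                   best$coefficients), collapse = "; "),
      rss = best$rss, aicc = best$aicc, converged = best$converged)
  }
  spi_fams <- c("exp_decay", "exp_linear", "cubic", "linear")
  add("Interface rugosity", "average", met$pressure, met$rugosity_mean, spi_fams)
  add("Interface rugosity", "SD", met$pressure, met$rugosity_sd, spi_fams)
  add("SPI penetration depth", "average", met$pressure, met$penetration_mean,
      spi_fams)
  add("SPI penetration depth", "SD", met$pressure, met$penetration_sd, spi_fams)
  add("Maerl live/dead ratio", "average", met$pressure, met$ratio_mean, spi_fams)
  add("Maerl live/dead ratio", "SD", met$pressure, met$ratio_sd, spi_fams)
  if (!is.null(thalli)) {
    ts <- merge(thalli$station, met[, c("station", "pressure")], by = "station")
    add("Thalli mean perimeter", "average", ts$pressure, ts$perimeter_mean,
        "linear")
    add("Thalli mean solidity", "average", ts$pressure, ts$solidity_mean,
        "linear")
  }
  list(table = do.call(rbind, rows), fits = fits)
}

#' @export
print.maerl_pipeline <- function(x, ...) {
  cat("maerl dredging-impact pipeline run\n")
  print(x$pressure)
  cat(sprintf("  %d images over %d stations; outputs in %s\n",
              nrow(x$image_metrics), nrow(x$station_summary$metrics),
              x$out_dir))
  invisible(x)
}

#' Plot the pipeline's figure set
#'
#' Writes the standard figure panel as PNG files: per-metric scatter plots of
#' station averages and SDs against dredging intensity with the best fitted
#' curve, group mean (+/- SE) vertical profile panels for live, dead and
#' interstitial space, and thalli morphology scatter plots when present. A
#' missing metric is skipped with a warning.
#'
#' @param bundle a `"maerl_pipeline"` result.
#' @param dir output directory (default `<out_dir>/figures`).
#' @return Invisibly, the written file paths.
#' @export
make_figures <- function(bundle, dir = file.path(bundle$out_dir, "figures")) {
  if (!capabilities("png"))
    stop("this R build has no png device available", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  met <- bundle$station_summary$metrics
  paths <- character()
  panel <- function(fname, draw) {
    f <- file.path(dir, fname)
    grDevices::png(f, width = 700, height = 500)
    on.exit(dev.off(), add = TRUE)
    draw()
    paths <<- c(paths, f)
  }
  specs <- list(
    c("rugosity_mean", "Interface rugosity (average)"),
    c("rugosity_sd", "Interface rugosity (SD)"),
    c("penetration_mean", "SPI penetration depth (average, cm)"),
    c("penetration_sd", "SPI penetration depth (SD, cm)"),
    c("ratio_mean", "Maerl live/dead ratio (average)"),
    c("ratio_sd", "Maerl live/dead ratio (SD)"))
  key <- c(rugosity_mean = "Interface rugosity average",
           rugosity_sd = "Interface rugosity SD",
           penetration_mean = "SPI penetration depth average",
           penetration_sd = "SPI penetration depth SD",
           ratio_mean = "Maerl live/dead ratio average",
           ratio_sd = "Maerl live/dead ratio SD")
  for (s in specs) {
    if (all(!is.finite(met[[s[1L]]]))) {
      warning("metric ", s[1L], " missing; plot skipped", call. = FALSE)
      next
    }
    panel(paste0("fig_", s[1L], ".png"), function() {
      plot(met$pressure, met[[s[1L]]],
           xlab = "dredging intensity (times fully dredged)", ylab = s[2L],
           pch = c(Control = 19, Moderate = 0, High = 17)[as.character(met$group)])
      fit <- bundle$fits$fits[[key[[s[1L]]]]]
      if (!is.null(fit)) {
        xs <- seq(min(met$pressure), max(met$pressure), length.out = 200)
        lines(xs, response_curve(fit, xs), lwd = 2)
      }
    })
  }
  prof <- bundle$station_summary$profiles
  depths <- seq(0, bundle$station_summary$max_depth_cm -
                  bundle$station_summary$bin_cm,
                by = bundle$station_summary$bin_cm)
  for (scl in c("mean", "sd")) {
    for (cls in c("live", "dead", "interstice")) {
      m <- prof[[scl]][[cls]]
      panel(sprintf("fig_profile_%s_%s.png", cls, scl), function() {
        plot(NA, xlim = range(m, 0, na.rm = TRUE),
             ylim = rev(range(depths)), yaxt = "n",
             xlab = sprintf("%% %s (%s)", cls, scl), ylab = "depth (cm)")
        axis(2, at = seq(0, max(depths) + 0.5, by = 0.5), las = 1,
             cex.axis = 0.5)
        gi <- 0
        for (g in levels(met$group)) {
          gi <- gi + 1
          sel <- met$group == g
          if (!any(sel)) next
          mu <- colMeans(m[sel, , drop = FALSE], na.rm = TRUE)
          lines(mu, depths, col = gi, lwd = 2)
          points(mu, depths, col = gi,
                 pch = c(Control = 19, Moderate = 0, High = 17)[[g]])
        }
        legend("bottomright", legend = levels(met$group), col = 1:3,
               pch = c(19, 0, 17), lwd = 2, cex = 0.8)
      })
    }
  }
  invisible(paths)
}
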