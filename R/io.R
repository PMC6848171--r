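#' Read and write the pipeline's file formats
#'
#' Images are 8-bit PNG (TIFF also readable when the `tiff` package is
#' available); interface traces and ping tables are plain CSV. Trace CSVs have
#' columns `column` (1-based pixel column) and `interface_row` (0-based count
#' of water rows above the interface in that column).
#'
#' @param path file path.
#' @param image RGB array (H x W x 3) or grayscale matrix with values 0-255.
#' @param trace numeric interface trace (see [classify_pixels()]).
#' @name maerl_io
NULL

#' @rdname maerl_io
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF needs the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(raw)) == 3L && dim(raw)[3L] >= 3L) raw <- raw[, , 1:3]
  round(raw * 255)
}

#' @rdname maerl_io
#' @export
write_image_png <- function(image, path) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname maerl_io
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(column = seq_along(trace), interface_row = trace),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname maerl_io
#' @export
read_trace <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("column", "interface_row") %in% names(d)))
  d$interface_row[order(d$column)]
}

#' @rdname maerl_io
#' @export
read_pings <- function(path) {
  d <- read.csv(path)
  need <- c("vessel_id", "timestamp", "x", "y", "speed", "season")
  if (!all(need %in% names(d)))
    stop("ping CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(d$in_fleet)) d$in_fleet <- TRUE
  d$in_fleet <- as.logical(d$in_fleet)
  d
}

# Write the complete rendered campaign file set under `dir`.
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spi_dir <- file.path(dir, "spi"); dir.create(spi_dir, showWarnings = FALSE)
  trace_dir <- file.path(dir, "traces"); dir.create(trace_dir, showWarnings = FALSE)
  thalli_dir <- file.path(dir, "thalli"); dir.create(thalli_dir, showWarnings = FALSE)

  it <- campaign$image_truth
  for (k in seq_len(nrow(it))) {
    scene <- render_campaign_image(campaign, it$station[k], it$image[k])
    stem <- paste0(it$station[k], "_", it$image[k])
    write_image_png(scene$image, file.path(spi_dir, paste0(stem, ".png")))
    write_trace(scene$trace, file.path(trace_dir, paste0(stem, ".csv")))
  }
  tt <- campaign$thalli_truth
  if (nrow(tt)) {
    for (key in unique(paste(tt$station, tt$core))) {
      parts <- strsplit(key, " ")[[1L]]
      scene <- render_campaign_core(campaign, parts[1L], parts[2L])
      write_image_png(scene$image,
                      file.path(thalli_dir,
                                paste0(parts[1L], "_", parts[2L], ".png")))
    }
    thalli_map <- unique(tt[, c("station", "core")])
    write.csv(thalli_map, file.path(dir, "thalli_map.csv"), row.names = FALSE)
  }
  write.csv(campaign$stations, file.path(dir, "stations.csv"),
            row.names = FALSE)
  write.csv(campaign$tracks$pings, file.path(dir, "pings.csv"),
            row.names = FALSE)
  list(dir = dir, spi = spi_dir, traces = trace_dir, thalli = thalli_dir,
       stations = file.path(dir, "stations.csv"),
       pings = file.path(dir, "pings.csv"),
       scale_cm_per_px = campaign$geometry$scale_cm_per_px)
}
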