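#' Write a movie as a multi-page 16-bit TIFF with a JSON metadata sidecar
#'
#' Pages are ordered frame-major, then Z, then channel (TZCYX). Because
#' the baseline TIFF container carries no physical calibration, the voxel
#' size, frame interval, channel map and array shape are written to
#' `<path>.json` next to the image; [read_movie()] restores the movie
#' bit-identically from the pair.
#'
#' @param movie a [timelapse_movie()] with intensities in 0..65535.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "timelapse_movie"))
  d <- dim(movie$data)
  .assert(max(movie$data) <= 65535, "intensities exceed the 16-bit range")
  pages <- vector("list", d[1] * d[3] * d[2])
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[3])) for (ch in seq_len(d[2])) {
    i <- i + 1L
    pages[[i]] <- matrix(movie$data[t, ch, z, , ], d[4], d[5]) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  meta <- list(shape = list(t = d[1], c = d[2], z = d[3], y = d[4], x = d[5]),
               page_order = "TZC",
               channels = as.list(movie$channels),
               voxel_size_um = as.list(movie$voxel_size),
               frame_interval_min = movie$frame_interval)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a calibrated movie from a multi-page TIFF
#'
#' Calibration and layout come from the JSON sidecar written by
#' [write_movie()]; without a sidecar, the shape, channel map, voxel size
#' and frame interval must all be supplied, otherwise an error explains
#' what is missing.
#'
#' @param path TIFF path.
#' @param channels optional channel-map override (named integer vector).
#' @param voxel_size,frame_interval optional calibration overrides.
#' @param shape optional `c(t, c, z)` layout override for sidecar-less
#'   files (pages must be in TZC order).
#' @return a [timelapse_movie()].
#' @export
read_movie <- function(path, channels = NULL, voxel_size = NULL,
                       frame_interval = NULL, shape = NULL) {
  .assert(file.exists(path), paste("file not found:", path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  if (is.null(meta) && (is.null(voxel_size) || is.null(frame_interval) ||
                        is.null(channels) || is.null(shape)))
    stop("no metadata sidecar found for ", path,
         ": supply channels, voxel_size, frame_interval and shape explicitly",
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- if (!is.null(meta)) {
    c(meta$shape$t, meta$shape$c, meta$shape$z, meta$shape$y, meta$shape$x)
  } else {
    c(shape[1], shape[2], shape[3], nrow(pages[[1]]), ncol(pages[[1]]))
  }
  dims <- as.integer(dims)
  .assert(length(pages) == dims[1] * dims[2] * dims[3],
          "page count does not match the declared shape")
  data <- array(0, dim = dims)
  i <- 0L
  for (t in seq_len(dims[1])) for (z in seq_len(dims[3])) for (ch in seq_len(dims[2])) {
    i <- i + 1L
    data[t, ch, z, , ] <- pages[[i]]
  }
  ch_map <- channels %||% unlist(meta$channels)
  vx <- as.numeric(voxel_size %||% unlist(meta$voxel_size_um))
  fi <- as.numeric(frame_interval %||% meta$frame_interval_min)
  .assert(all(vx > 0) && fi > 0, "calibration must be strictly positive")
  timelapse_movie(data, stats::setNames(as.integer(ch_map), names(ch_map)),
                  vx, fi)
}

#' Write ground-truth tracks as CSV
#'
#' @param truth a `ground_truth`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.csv(truth$tracks, path, row.names = FALSE)
  invisible(path)
}
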