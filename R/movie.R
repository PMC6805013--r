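# calibrated multi-channel movies and labelled mask stacks

#' Calibrated multi-channel time-lapse movie
#'
#' A light container for fluorescence movies: a named list of `H x W x T`
#' intensity arrays sharing one pixel grid, plus the spatial and temporal
#' calibration needed to report physical quantities. An optional camera dark
#' frame is subtracted before any intensity-based analysis.
#'
#' @param channels named list of numeric `H x W x T` arrays (row, column,
#'   frame), all of identical dimension, non-negative intensities.
#' @param pixel_size pixel edge length in micrometres.
#' @param frame_interval time between frames in seconds.
#' @param dark_frame optional `H x W` camera offset image subtracted from
#'   every frame of every channel before analysis.
#' @return an object of class `cell_movie`.
#' @export
cell_movie <- function(channels, pixel_size, frame_interval, dark_frame = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, identity))) != 1 || length(dims[[1]]) != 3) {
    stop("all channels must be H x W x T arrays of identical dimension")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  if (!is.null(dark_frame)) {
    stopifnot(identical(dim(dark_frame), dims[[1]][1:2]))
  }
  structure(
    list(
      channels = channels, pixel_size = pixel_size,
      frame_interval = frame_interval, dark_frame = dark_frame
    ),
    class = "cell_movie"
  )
}

#' @export
print.cell_movie <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<cell_movie> %d x %d px, %d frames, channels: %s\n  %.3g um/px, %.3g s/frame%s\n",
    d[1], d[2], d[3], paste(names(x$channels), collapse = ", "),
    x$pixel_size, x$frame_interval,
    if (is.null(x$dark_frame)) "" else ", dark frame attached"
  ))
  invisible(x)
}

n_frames <- function(movie) dim(movie$channels[[1]])[3]

# channel frame with dark-frame subtraction (clamped at zero)
dark_subtracted <- function(movie, channel, frame) {
  img <- movie$channels[[channel]][, , frame]
  if (!is.null(movie$dark_frame)) {
    img <- pmax(img - movie$dark_frame, 0)
  }
  img
}

#' Per-frame labelled segmentation masks
#'
#' Integer label arrays aligned with a movie: 0 is background and each
#' positive label is one 4-connected region; labels are contiguous
#' `1..K` within every frame.
#'
#' @param labels integer `H x W x T` array.
#' @param provenance character note recording the channel and method that
#'   produced the masks.
#' @param pixel_size,frame_interval calibration copied from the source movie.
#' @return an object of class `mask_stack`.
#' @export
mask_stack <- function(labels, provenance = "unknown", pixel_size = 1,
                       frame_interval = 1) {
  stopifnot(length(dim(labels)) == 3)
  structure(
    list(
      labels = labels, provenance = provenance,
      pixel_size = pixel_size, frame_interval = frame_interval
    ),
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$labels)
  n <- max(x$labels)
  cat(sprintf(
    "<mask_stack> %d x %d px, %d frames, max label %d (%s)\n",
    d[1], d[2], d[3], n, x$provenance
  ))
  invisible(x)
}

#' Write a movie as multi-page TIFF files plus a JSON sidecar
#'
#' One TIFF stack per channel (32-bit float, one page per frame) and a
#' `<stem>.json` sidecar holding calibration and, when supplied, the
#' generator ground truth.
#'
#' @param movie a [cell_movie()].
#' @param stem path stem; files are written as `<stem>_<channel>.tif`.
#' @param ground_truth optional list stored verbatim in the sidecar.
#' @return invisibly, the paths written.
#' @export
write_movie_tiff <- function(movie, stem, ground_truth = NULL) {
  paths <- character(0)
  scales <- numeric(0)
  for (ch in names(movie$channels)) {
    arr <- movie$channels[[ch]]
    # the TIFF writer stores floats in [0, 1]; normalize per channel and
    # record the scale in the sidecar
    sc <- max(arr, 1e-300)
    pages <- lapply(seq_len(dim(arr)[3]), function(t) arr[, , t] / sc)
    p <- paste0(stem, "_", ch, ".tif")
    tiff::writeTIFF(pages, p, bits.per.sample = 32L, reduce = FALSE)
    paths <- c(paths, p)
    scales <- c(scales, sc)
  }
  meta <- list(
    channels = names(movie$channels),
    channel_scales = as.list(setNames(scales, names(movie$channels))),
    pixel_size_um = movie$pixel_size,
    frame_interval_s = movie$frame_interval,
    n_frames = n_frames(movie)
  )
  if (!is.null(ground_truth)) meta$ground_truth <- ground_truth
  jp <- paste0(stem, ".json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, jp))
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param stem path stem used when writing.
#' @return a [cell_movie()]; the sidecar's ground truth, if present, is
#'   attached as attribute `"ground_truth"`.
#' @export
read_movie_tiff <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  channels <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(paste0(stem, "_", ch, ".tif"), all = TRUE)
    sc <- meta$channel_scales[[ch]] %||% 1
    channels[[ch]] <- array(
      unlist(pages) * sc,
      dim = c(dim(pages[[1]]), length(pages))
    )
  }
  mv <- cell_movie(channels, meta$pixel_size_um, meta$frame_interval_s)
  if (!is.null(meta$ground_truth)) attr(mv, "ground_truth") <- meta$ground_truth
  mv
}
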