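#' Camera configuration
#'
#' The virtual sCMOS camera runs in free-run mode: it publishes one frame
#' every `exposure_us` microseconds, reading out only a central
#' `area` window (default 128 x 128) of a notional 2048 x 2048 sensor.
#'
#' @param exposure_us frame interval in integer microseconds (2000 us =
#'   500 frames/s).
#' @param area integer `(rows, cols)` readout window.
#' @param sensor full sensor dimensions, for bounds checking only.
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(exposure_us = 2000L, area = c(128L, 128L),
                          sensor = c(2048L, 2048L)) {
  exposure_us <- as.integer(exposure_us)
  area <- as.integer(area)
  if (is.na(exposure_us) || exposure_us <= 0L)
    stop("exposure_us must be a positive integer")
  if (length(area) != 2L || any(area < 1L) || any(area > sensor))
    stop("readout area must lie within the sensor bounds")
  structure(list(exposure_us = exposure_us, area = area,
                 sensor = as.integer(sensor), mode = "free-run"),
            class = "camera_config")
}

new_frame <- function(pixels, camera_timestamp, frame_index) {
  structure(list(pixels = pixels,
                 camera_timestamp = as.numeric(camera_timestamp),
                 frame_index = as.integer(frame_index)),
            class = "vt_frame")
}

#' Open a virtual camera over simulated tissue
#'
#' Returns a frame source: polled at successive multiples of the exposure
#' time by the event engine, it renders the tissue and publishes frames
#' whose camera timestamp is exactly `frame_index * exposure_us` (integer
#' arithmetic, no drift). Frame indices start at 0.
#'
#' @param config a [camera_config()].
#' @param params a [tissue_params()]; the source owns a fresh quiescent
#'   [tissue_state()].
#' @return A `frame_source` of kind `"virtual"`.
#' @export
open_virtual_camera <- function(config, params) {
  if (!inherits(config, "camera_config")) stop("config must be a camera_config")
  if (!inherits(params, "tissue_params")) stop("params must be tissue_params")
  if (!all(params$grid_shape == config$area))
    stop("camera area must match the tissue grid")
  structure(list(kind = "virtual", config = config, params = params,
                 state = tissue_state(params)),
            class = "frame_source")
}

#' Replay a recorded stack as a frame source
#'
#' Frames are re-emitted with their recorded camera timestamps, e.g. to
#' re-run the real-time analysis offline on saved data.
#'
#' @param frames list of `vt_frame` objects (as from [load_stack()]).
#' @return A `frame_source` of kind `"replay"`.
#' @export
replay_source <- function(frames) {
  if (length(frames) > 1L) {
    ts <- vapply(frames, `[[`, numeric(1), "camera_timestamp")
    if (any(diff(ts) <= 0))
      stop("recorded timestamps must be strictly increasing")
  }
  structure(list(kind = "replay", frames = frames), class = "frame_source")
}

#' Single-slot latest-frame hand-off
#'
#' Models the camera-to-imaging-loop hand-off: the slot holds at most one
#' frame, and publishing over an unread frame discards it (that frame is
#' "lost") and increments `overwrites`. This is what produces frame loss
#' when the consumer is slower than the frame interval.
#'
#' @return A mutable environment of class `frame_slot` with fields
#'   `current` (frame or `NULL`), `produced`, `taken`, `overwrites`.
#' @export
frame_slot <- function() {
  s <- new.env(parent = emptyenv())
  s$current <- NULL
  s$produced <- 0L
  s$taken <- 0L
  s$overwrites <- 0L
  class(s) <- "frame_slot"
  s
}

#' Publish a frame into the slot
#'
#' @param slot a [frame_slot()].
#' @param f a frame.
#' @return The slot, invisibly (mutated in place).
#' @export
publish <- function(slot, f) {
  if (!is.null(slot$current)) slot$overwrites <- slot$overwrites + 1L
  slot$current <- f
  slot$produced <- slot$produced + 1L
  invisible(slot)
}

#' Take the current frame from the slot
#'
#' @param slot a [frame_slot()].
#' @return The frame, or `NULL` if the slot is empty.
#' @export
slot_take <- function(slot) {
  f <- slot$current
  if (!is.null(f)) {
    slot$current <- NULL
    slot$taken <- slot$taken + 1L
  }
  f
}

timestamp_filename <- function(ts_us) {
  sprintf("%012.0f.tif", ts_us)
}

#' Save frames as a TIFF stack directory
#'
#' Writes one single-image, uncompressed, 16-bit grayscale TIFF per frame.
#' The camera timestamp (microseconds, zero-padded to 12 digits so that
#' lexicographic order equals acquisition order) is the filename.
#'
#' @param frames list of `vt_frame` objects.
#' @param out_dir output directory (created if needed).
#' @return Number of files written.
#' @export
save_stack <- function(frames, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ts <- vapply(frames, `[[`, numeric(1), "camera_timestamp")
  if (anyDuplicated(ts))
    stop("duplicate camera timestamps: corrupted timestamping")
  for (f in frames) {
    tiff::writeTIFF(f$pixels / 65535,
                    file.path(out_dir, timestamp_filename(f$camera_timestamp)),
                    bits.per.sample = 16L, compression = "none")
  }
  length(frames)
}

#' Load a TIFF stack directory
#'
#' Reads every `*.tif` written by [save_stack()], recovers camera
#' timestamps from the filenames, sorts by timestamp and assigns frame
#' indices in that order (starting at 0).
#'
#' @param in_dir directory containing only stack TIFFs.
#' @param area expected `(rows, cols)`; images of any other shape or bit
#'   depth are a format error.
#' @return List of `vt_frame` objects (possibly empty).
#' @export
load_stack <- function(in_dir, area = c(128L, 128L)) {
  files <- list.files(in_dir, pattern = "\\.tif$", full.names = TRUE)
  if (length(files) == 0L) return(list())
  ts <- as.numeric(sub("\\.tif$", "", basename(files)))
  if (anyNA(ts)) stop("non-timestamp TIFF filename in stack directory")
  o <- order(ts)
  files <- files[o]; ts <- ts[o]
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    m <- tiff::readTIFF(files[i], as.is = TRUE)
    if (!is.matrix(m) || !identical(dim(m), as.integer(area)))
      stop(sprintf("frame %s is not a %d x %d single-channel image",
                   basename(files[i]), area[1L], area[2L]))
    if (max(m) > 65535L || storage.mode(m) != "integer")
      stop("frame is not 16-bit unsigned")
    frames[[i]] <- new_frame(m, ts[i], i - 1L)
  }
  frames
}

#' Per-pair effective frame rate from acquired frames
#'
#' Mirrors the imaging loop's frame-rate monitor: for each consecutive pair
#' of acquired frames, `1 / dt` in frames per second. With no frame loss
#' and zero processing cost this is exactly `1e6 / exposure_us`.
#'
#' @param log a `session_log` (see [run_session()]).
#' @return Numeric vector of rate samples (frames/s).
#' @export
effective_frame_rate <- function(log) {
  ts <- log$frames$camera_timestamp_us[log$frames$status != "lost"]
  if (length(ts) < 2L)
    stop("need at least two acquired frames to estimate a frame rate")
  1e6 / diff(ts)
}
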