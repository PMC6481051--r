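#' Rectangular detection ROI in pixel coordinates
#'
#' @param row0,col0 1-based top-left pixel of the ROI.
#' @param nrow,ncol ROI extent in pixels.
#' @return An object of class `vt_roi`.
#' @export
roi_px <- function(row0, col0, nrow, ncol) {
  row0 <- as.integer(row0); col0 <- as.integer(col0)
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (nrow < 1L || ncol < 1L) stop("ROI must contain at least one pixel")
  if (row0 < 1L || col0 < 1L) stop("ROI must start inside the frame")
  structure(list(row0 = row0, col0 = col0, nrow = nrow, ncol = ncol),
            class = "vt_roi")
}

#' Resolve an ROI given in mm to pixel coordinates
#'
#' Pixels whose centers fall in the half-open rectangle
#' `[x, x+w) x [y, y+h)` form the ROI; e.g. a 0.1 x 0.3 mm window at the
#' heart base. Errors if no pixel center falls inside.
#'
#' @param corner_mm `(x, y)` top-left corner, mm.
#' @param size_mm `(w, h)`, mm.
#' @param params a [tissue_params()].
#' @return A `vt_roi`.
#' @export
roi_from_mm <- function(corner_mm, size_mm, params) {
  m <- make_rect_mask(corner_mm, size_mm, params)
  idx <- which(m$pixels, arr.ind = TRUE)
  roi_px(min(idx[, 1L]), min(idx[, 2L]),
         max(idx[, 1L]) - min(idx[, 1L]) + 1L,
         max(idx[, 2L]) - min(idx[, 2L]) + 1L)
}

roi_indices <- function(roi, grid_shape) {
  rows <- roi$row0:(roi$row0 + roi$nrow - 1L)
  cols <- roi$col0:(roi$col0 + roi$ncol - 1L)
  if (max(rows) > grid_shape[1L] || max(cols) > grid_shape[2L])
    stop("ROI extends outside the frame")
  as.vector(outer(rows, cols, function(r, c) (c - 1L) * grid_shape[1L] + r))
}

#' Real-time detector configuration
#'
#' Houses the detection ROI, the dF/F threshold `th` and the length of the
#' shift-register buffer of past ROI means.
#'
#' @param roi a [roi_px()] / [roi_from_mm()] region.
#' @param th threshold on the relative fluorescence variation, as a
#'   fraction (0.01 = 1%); must lie strictly in (0, 1).
#' @param buffer_len maximum number of stored ROI means (>= 1).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(roi, th = 0.01, buffer_len = 10L) {
  if (!inherits(roi, "vt_roi")) stop("roi must be a vt_roi")
  if (!is.finite(th) || th <= 0 || th >= 1)
    stop("th must lie strictly in (0, 1)")
  buffer_len <- as.integer(buffer_len)
  if (buffer_len < 1L) stop("buffer_len must be >= 1")
  structure(list(roi = roi, th = th, buffer_len = buffer_len),
            class = "detector_config")
}

#' Mean fluorescence within an ROI
#'
#' @param pixels frame matrix (counts).
#' @param roi a `vt_roi`.
#' @return Arithmetic mean of the ROI pixels, in counts (not rounded).
#' @export
roi_mean <- function(pixels, roi) {
  rows <- roi$row0:(roi$row0 + roi$nrow - 1L)
  cols <- roi$col0:(roi$col0 + roi$ncol - 1L)
  if (max(rows) > nrow(pixels) || max(cols) > ncol(pixels))
    stop("ROI extends outside the frame")
  mean(pixels[rows, cols])
}

#' Relative fluorescence variation against the buffer
#'
#' Element-wise `(buffer_i - m) / buffer_i`, preserving buffer order.
#' Positive values indicate a fluorescence *drop* relative to that buffer
#' entry — the signature of depolarization for a negative-going VSD.
#'
#' @param buffer numeric vector of past ROI means (oldest first), all > 0.
#' @param m current ROI mean.
#' @return Numeric vector of fractions, same length as `buffer`.
#' @export
relative_variation <- function(buffer, m) {
  if (length(buffer) == 0L) stop("buffer is empty")
  if (any(buffer == 0)) stop("zero buffer entry: relative variation undefined")
  (buffer - m) / buffer
}

#' Threshold test on the relative-variation vector
#'
#' A depolarization event is detected iff any element of
#' [relative_variation()] is strictly greater than `th` (boundary equality
#' does not trigger).
#'
#' @inheritParams relative_variation
#' @param th detection threshold (fraction).
#' @return Logical scalar.
#' @export
detect <- function(buffer, m, th) {
  any(relative_variation(buffer, m) > th)
}

#' Fresh detector state
#'
#' The mutable shift-register buffer of past ROI means plus the armed flag
#' (lowered for the duration of a stimulation protocol).
#'
#' @param cfg a [detector_config()].
#' @return An environment of class `detector_state`.
#' @export
detector_state <- function(cfg) {
  st <- new.env(parent = emptyenv())
  st$buf <- numeric(0)
  st$armed <- TRUE
  st$last_event_time <- NA_real_
  st$cfg <- cfg
  class(st) <- "detector_state"
  st
}

#' One real-time analysis cycle
#'
#' First cycle: the buffer is empty, so `m` is stored and no comparison is
#' made. Later cycles: if the detector is armed and the buffer comparison
#' crosses the threshold, a detection event is emitted and the triggering
#' `m` is *not* appended (the stimulation protocol takes over and the
#' buffer will be reset); otherwise `m` is appended, evicting the oldest
#' entry when the buffer is full.
#'
#' @param state a [detector_state()] (mutated in place).
#' @param m current ROI mean.
#' @param t_us analysis completion time, microseconds.
#' @return A detection event `list(time_us, rel_variation)` or `NULL`.
#' @export
detector_step <- function(state, m, t_us) {
  cfg <- state$cfg
  if (length(state$buf) == 0L) {
    state$buf <- m
    return(NULL)
  }
  if (state$armed) {
    rv <- (state$buf - m) / state$buf
    if (any(rv > cfg$th)) {
      state$last_event_time <- t_us
      return(list(time_us = t_us, rel_variation = max(rv)))
    }
  }
  if (length(state$buf) >= cfg$buffer_len) {
    state$buf <- c(state$buf[-1L], m)
  } else {
    state$buf <- c(state$buf, m)
  }
  NULL
}

#' Reset the detector buffer (protocol end)
#'
#' @param state a [detector_state()].
#' @param armed new armed status.
#' @return The state, invisibly.
#' @export
detector_reset <- function(state, armed = TRUE) {
  state$buf <- numeric(0)
  state$armed <- armed
  invisible(state)
}
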