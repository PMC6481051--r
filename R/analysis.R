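#' Extract an ROI fluorescence trace from a stack
#'
#' @param frames non-empty list of `vt_frame` objects.
#' @param roi a `vt_roi`.
#' @return An object of class `vt_trace`: `times_us`, `values` (ROI mean
#'   per frame, counts) and the `roi` used.
#' @export
extract_trace <- function(frames, roi) {
  if (length(frames) == 0L) stop("empty stack")
  structure(list(
    times_us = vapply(frames, `[[`, numeric(1), "camera_timestamp"),
    values = vapply(frames, function(f) roi_mean(f$pixels, roi), numeric(1)),
    roi = roi
  ), class = "vt_trace")
}

#' Fractional fluorescence change of a trace
#'
#' `(F0 - F_t) / F0` with `F0` the mean over a baseline window preceding
#' activity; positive during depolarization (negative-going dye).
#'
#' @param trace a `vt_trace`.
#' @param baseline integer indices of the baseline samples.
#' @return Numeric vector of dF/F values, one per trace sample.
#' @export
dff <- function(trace, baseline = seq_len(min(10L, length(trace$values)))) {
  if (length(baseline) == 0L) stop("baseline window is empty")
  f0 <- mean(trace$values[baseline])
  if (f0 == 0) stop("zero baseline fluorescence")
  (f0 - trace$values) / f0
}

#' Offline re-detection: the oracle for the online detector
#'
#' Replays the real-time buffer comparison over a recorded trace, sample
#' by sample. After each of its own detections it blanks the protocol
#' window `(t, t + blank_us)` — skipping samples inside it and clearing
#' the buffer at its end — exactly as the online loop disarms during a
#' stimulation protocol. Explicit `blanked` intervals (e.g. taken from a
#' session log) may be supplied instead.
#'
#' @param trace a `vt_trace`.
#' @param cfg a [detector_config()].
#' @param blank_us protocol-window length after each detection
#'   (pre + pulse + post delays), microseconds. Ignored if `blanked` given.
#' @param blanked optional two-column matrix of `[start, end)` intervals.
#' @return Numeric vector of event times (us).
#' @export
offline_detect <- function(trace, cfg, blank_us = 0, blanked = NULL) {
  st <- detector_state(cfg)
  events <- numeric(0)
  block_until <- -Inf
  for (i in seq_along(trace$values)) {
    t <- trace$times_us[i]
    if (!is.null(blanked)) {
      inside <- any(t >= blanked[, 1L] & t < blanked[, 2L])
      was_blocked <- i > 1L &&
        any(trace$times_us[i - 1L] >= blanked[, 1L] &
            trace$times_us[i - 1L] < blanked[, 2L])
      if (inside) next
      if (was_blocked) detector_reset(st)
    } else {
      if (t < block_until) next
      if (is.finite(block_until)) {        # first sample past the window
        detector_reset(st)
        block_until <- -Inf
      }
    }
    ev <- detector_step(st, trace$values[i], t)
    if (!is.null(ev)) {
      events <- c(events, t)
      if (is.null(blanked)) block_until <- t + blank_us
    }
  }
  events
}

#' Cycle-length statistics of a detected rhythm
#'
#' Periods are consecutive differences of event times; the spread uses the
#' population standard deviation. A coefficient of variation far below one
#' frame interval over the mean period indicates a stable simulated
#' tachycardia.
#'
#' @param event_times_us numeric vector of at least 3 event times (us).
#' @return A list of class `cycle_stats`: `event_times_us`,
#'   `mean_period_us`, `sd_period_us`, `cv_period`, `n_periods`.
#' @export
cycle_stats <- function(event_times_us) {
  if (length(event_times_us) < 3L)
    stop("need at least 3 events for cycle statistics (no sustained rhythm)")
  p <- diff(sort(event_times_us))
  mp <- mean(p)
  sdp <- sqrt(mean((p - mp)^2))   # population SD
  structure(list(event_times_us = event_times_us, mean_period_us = mp,
                 sd_period_us = sdp, cv_period = sdp / mp,
                 n_periods = length(p)),
            class = "cycle_stats")
}

#' Closed-form bound on the re-entry period
#'
#' For the loop geometry (stimulus mask, detection ROI, conduction
#' velocity) the cycle length is the pre-activation delay plus the wave
#' travel time from the stimulus to the ROI plus the detection latency.
#' The travel time is bounded by the nearest/farthest ROI-pixel distance
#' to the stimulus mask divided by cv. The detection latency is the part
#' of the upstroke needed for dF/F to cross the threshold
#' (`upstroke * th / sensitivity`) plus up to two frame intervals: one of
#' sampling quantization, and one because the shift-register buffer is
#' empty after each protocol reset, so the first analyzed frame only
#' seeds it and comparison resumes at the next frame. The protocol window
#' itself (`pre + pulse + post` plus the seeding frame) is a floor on the
#' cycle length. Returned as an interval `[min, max]` in us.
#'
#' @param config a closed-loop [run_config()].
#' @return Numeric length-2 vector `c(min_us, max_us)`.
#' @export
predict_period <- function(config) {
  stopifnot(inherits(config, "vt_config"))
  if (is.null(config$detector) || is.null(config$protocol))
    stop("predict_period needs the closed-loop geometry")
  tp <- config$tissue
  prot <- config$protocol
  exposure <- config$camera$exposure_us
  d <- mask_distance_mm(prot$mask, tp)
  idx <- roi_indices(config$detector$roi, tp$grid_shape)
  d_roi <- d[idx]
  t_cross_us <- tp$upstroke_ms * 1000 * config$detector$th / tp$sensitivity
  floor_us <- prot$pulse_us + prot$post_delay_us   # window beyond pre_delay
  lo <- prot$pre_delay_us +
    max(min(d_roi) / tp$cv_mm_ms * 1000 + t_cross_us, floor_us + exposure)
  hi <- prot$pre_delay_us +
    max(max(d_roi) / tp$cv_mm_ms * 1000 + t_cross_us, floor_us) +
    2 * exposure
  c(lo, hi)
}

#' Imaging-loop error rate
#'
#' Fraction of produced frames lost (overwritten before the imaging loop
#' read them) over the session.
#'
#' @param log a `session_log`.
#' @return Fraction in `[0, 1]`.
#' @export
il_error_rate <- function(log) {
  if (log$produced < 1L) stop("no frames produced")
  log$lost / log$produced
}

#' Real-time analysis-loop error rate
#'
#' Fraction of acquired frames the RTL failed to analyze because it was
#' still busy, excluding intentional protocol-window skips from both
#' numerator and denominator (those measure protocol design, not
#' analysis capacity).
#'
#' @param log a `session_log` from a closed-loop run.
#' @return Fraction in `[0, 1]`.
#' @export
rtl_error_rate <- function(log) {
  if (log$mode != "closed-loop") stop("RTL was not enabled in this session")
  denom <- log$acquired - log$skipped_protocol
  if (denom == 0L) return(0)
  log$skipped_busy / denom
}

#' Per-pixel activation-time map
#'
#' Activation time is estimated as the midpoint of the frame pair with the
#' steepest fluorescence *decrease* (matching the negative-going dye),
#' restricted to an optional time window. Pixels whose peak-to-trough
#' amplitude stays below `min_drop` counts are marked `NA` (no activity).
#'
#' @param frames list of `vt_frame` objects.
#' @param min_drop amplitude gate in counts; defaults to half the
#'   full-depolarization amplitude when `params` is given, else a quarter
#'   of the largest per-pixel range in the stack.
#' @param window_us optional `c(t0, t1)` restricting the search.
#' @param params optional [tissue_params()] (for the default gate).
#' @return Numeric `rows x cols` matrix of activation times (us), `NA`
#'   where no activation was found.
#' @export
activation_map <- function(frames, min_drop = NULL, window_us = NULL,
                           params = NULL) {
  if (length(frames) < 2L) stop("need at least two frames")
  ts <- vapply(frames, `[[`, numeric(1), "camera_timestamp")
  if (!is.null(window_us)) {
    keep <- ts >= window_us[1L] & ts <= window_us[2L]
    frames <- frames[keep]; ts <- ts[keep]
    if (length(frames) < 2L) stop("fewer than two frames in the window")
  }
  dims <- dim(frames[[1L]]$pixels)
  a <- vapply(frames, function(f) as.numeric(f$pixels),
              numeric(prod(dims)))           # pixels x time
  rng <- apply(a, 1L, function(v) max(v) - min(v))
  if (is.null(min_drop)) {
    min_drop <- if (!is.null(params)) 0.5 * params$sensitivity * params$f0
                else 0.25 * max(rng)
  }
  dv <- a[, -1L, drop = FALSE] - a[, -ncol(a), drop = FALSE]
  steepest <- max.col(-dv, ties.method = "first")
  t_mid <- (ts[-1L] + ts[-length(ts)]) / 2
  out <- t_mid[steepest]
  out[rng < min_drop | rng == 0] <- NA_real_
  matrix(out, dims[1L], dims[2L])
}

#' Recover conduction velocity from an activation map
#'
#' Regresses activation time on distance from the stimulus site: for a
#' wave expanding from a point-like source, time = intercept + d / cv, so
#' the fitted slope's reciprocal estimates cv.
#'
#' @param amap matrix from [activation_map()] (us).
#' @param origin_mm `(x, y)` of the wave source, mm.
#' @param params a [tissue_params()] (pixel geometry).
#' @return Estimated conduction velocity, mm/ms.
#' @export
estimate_cv <- function(amap, origin_mm, params) {
  ctr <- pixel_centers(params)
  t_ms <- as.vector(amap) / 1000
  d_mm <- sqrt((ctr$x - origin_mm[1L])^2 + (ctr$y - origin_mm[2L])^2)
  ok <- !is.na(t_ms)
  if (sum(ok) < 3L) stop("too few activated pixels to fit a wave speed")
  fit <- stats::lm(t_ms[ok] ~ d_mm[ok])
  1 / unname(stats::coef(fit)[2L])
}
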