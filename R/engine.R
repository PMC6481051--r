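#' Three-phase stimulation protocol
#'
#' On detection, the system waits `pre_delay_us` (the re-entry "clock"),
#' turns the patterned light on for `pulse_us`, then waits `post_delay_us`
#' before clearing the buffer and re-arming the detector. The post delay
#' blanks fluorescence artifacts of the stimulus itself. Imaging continues
#' uninterrupted throughout.
#'
#' @param mask a `stim_mask` (the projected light pattern).
#' @param pre_delay_us,pulse_us,post_delay_us protocol phases, integer
#'   microseconds; delays >= 0, pulse > 0.
#' @param amplitude light-intensity label (e.g. mW/mm^2); logged only — the
#'   activation-time tissue model does not grade with intensity.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(mask, pre_delay_us = 200000L, pulse_us = 5000L,
                          post_delay_us = 5000L, amplitude = NA_real_) {
  if (!inherits(mask, "stim_mask")) stop("mask must be a stim_mask")
  if (pre_delay_us < 0 || post_delay_us < 0) stop("delays must be >= 0")
  if (pulse_us <= 0) stop("pulse_us must be > 0")
  structure(list(mask = mask, pre_delay_us = as.numeric(pre_delay_us),
                 pulse_us = as.numeric(pulse_us),
                 post_delay_us = as.numeric(post_delay_us),
                 amplitude = amplitude),
            class = "stim_protocol")
}

#' Processing-cost model for the two loops
#'
#' Abstracts data-transfer and workstation load: the imaging loop occupies
#' `il_cost_us` per frame (read-out, stacking, rate check) and the analysis
#' loop `rtl_cost_us` per analyzed frame. An optional uniform jitter is
#' added to each (seeded, deterministic). Costs below the exposure time
#' reproduce the platform's stable regime; above it, frames are lost or
#' skipped.
#'
#' @param il_cost_us,rtl_cost_us base per-frame costs, microseconds (>= 0).
#' @param il_jitter_us,rtl_jitter_us width of a uniform `[0, jitter)`
#'   addition per frame (0 = constant cost).
#' @return An object of class `load_model`.
#' @export
load_model <- function(il_cost_us = 0, rtl_cost_us = 0,
                       il_jitter_us = 0, rtl_jitter_us = 0) {
  if (il_cost_us < 0 || rtl_cost_us < 0 || il_jitter_us < 0 ||
      rtl_jitter_us < 0)
    stop("costs and jitters must be >= 0")
  structure(list(il_cost_us = il_cost_us, rtl_cost_us = rtl_cost_us,
                 il_jitter_us = il_jitter_us, rtl_jitter_us = rtl_jitter_us),
            class = "load_model")
}

#' Assemble a full run configuration
#'
#' @param tissue a [tissue_params()].
#' @param camera a [camera_config()].
#' @param detector a [detector_config()] (required in closed-loop mode).
#' @param protocol a [stim_protocol()] (required in closed-loop mode).
#' @param load a [load_model()].
#' @param mode `"free-run"` (optical mapping only) or `"closed-loop"`.
#' @param duration_us session length, microseconds.
#' @param init_stim_us time of the single initiating apex stimulus (the
#'   external beat that starts the re-entrant circuit), or `NA` for none.
#' @param seed integer RNG seed; overrides `tissue$seed` when given.
#' @return An object of class `vt_config`.
#' @export
run_config <- function(tissue = tissue_params(),
                       camera = camera_config(),
                       detector = NULL,
                       protocol = NULL,
                       load = load_model(),
                       mode = c("closed-loop", "free-run"),
                       duration_us = 10e6,
                       init_stim_us = NA_real_,
                       seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "closed-loop") {
    if (is.null(detector)) stop("closed-loop mode requires a detector config")
    if (is.null(protocol)) stop("closed-loop mode requires a stim protocol")
  }
  if (!is.na(init_stim_us) && is.null(protocol))
    stop("an initiating stimulus requires a stim protocol (for its mask)")
  if (duration_us < 0) stop("duration_us must be >= 0")
  if (!is.null(seed)) tissue$seed <- as.integer(seed)
  if (!is.null(detector))
    roi_indices(detector$roi, tissue$grid_shape)  # bounds check
  structure(list(tissue = tissue, camera = camera, detector = detector,
                 protocol = protocol, load = load, mode = mode,
                 duration_us = as.numeric(duration_us),
                 init_stim_us = as.numeric(init_stim_us)),
            class = "vt_config")
}

#' Run a simulated imaging / closed-loop session
#'
#' Executes the platform's two asynchronous tasks on a deterministic
#' discrete-event clock. The virtual camera publishes a frame into the
#' single-slot hand-off every `exposure_us`; the imaging loop (IL) reads
#' the newest frame as soon as it is free (frames overwritten unread are
#' lost); in closed-loop mode the real-time analysis loop (RTL) computes
#' the ROI mean of each IL-read frame — unless the detector is inside a
#' stimulation protocol window ("protocol-window" skip) or the RTL is
#' still busy ("rtl-busy" skip) — and runs the buffer comparison. A
#' detection fires the three-phase [stim_protocol()], whose light pulse
#' excites the tissue via [apply_stimulus()] at pulse onset.
#'
#' Every produced frame gets exactly one per-frame record with its fate:
#' `analyzed`, `protocol-window`, `rtl-busy`, `rtl-off` (free-run), or
#' `lost`. Identical configurations (including seed) give bit-identical
#' results. With `keep_frames = FALSE` only the detection-ROI pixels are
#' rendered (the session log is complete but pixel data are not retained);
#' the RNG stream then differs from a full-frame run.
#'
#' @param config a [run_config()].
#' @param keep_frames keep (and return) full frames? Default `TRUE`.
#' @return A list of class `vt_session`: `frames` (list of `vt_frame`, or
#'   `NULL`) and `log` (a `session_log` with data frames `frames`,
#'   `detections`, `stims`, plus counters).
#' @export
run_session <- function(config, keep_frames = TRUE) {
  stopifnot(inherits(config, "vt_config"))
  tp <- config$tissue
  exposure <- config$camera$exposure_us
  if (!all(tp$grid_shape == config$camera$area))
    stop("camera area must match the tissue grid")
  set.seed(tp$seed)
  closed <- config$mode == "closed-loop"

  n <- as.integer(floor(config$duration_us / exposure))
  state <- tissue_state(tp)
  det <- if (closed) detector_state(config$detector) else NULL
  roi_idx <- if (closed) roi_indices(config$detector$roi, tp$grid_shape)
             else NULL
  prot <- config$protocol
  ld <- config$load
  jitter <- function(w) if (w > 0) stats::runif(1L, 0, w) else 0

  # pending stimulus times (us), sorted; the initiating beat seeds it
  stim_q <- if (!is.na(config$init_stim_us)) config$init_stim_us else numeric(0)

  frames <- if (keep_frames) vector("list", n) else NULL
  status <- character(n)
  read_time <- rep(NA_real_, n)
  det_t <- numeric(0); det_k <- integer(0); det_rv <- numeric(0)
  stim_on <- numeric(0); stim_off <- numeric(0)

  il_ready <- 0; rtl_ready <- 0
  rearm_at <- -Inf    # detector re-arms (buffer cleared) at this time
  win_start <- Inf    # start of the current protocol (disarm) window
  k <- 0L
  while (k < n) {
    t_pub <- k * exposure
    # fire any scheduled stimuli due before this frame
    while (length(stim_q) > 0L && stim_q[1L] <= t_pub) {
      apply_stimulus(state, prot$mask, stim_q[1L])
      stim_q <- stim_q[-1L]
    }
    # camera renders the frame at publish time
    if (keep_frames) {
      px <- render_frame(state, t_pub)
      frames[[k + 1L]] <- new_frame(px, t_pub, k)
      m <- if (closed) mean(px[roi_idx]) else NA_real_
    } else {
      m <- if (closed) mean(render_frame(state, t_pub, pixels = roi_idx))
           else { advance_state(state, t_pub); NA_real_ }
    }
    # imaging loop: read the slot before the next publish overwrites it
    deadline <- if (k < n - 1L) (k + 1L) * exposure else config$duration_us
    r <- max(t_pub, il_ready)
    readable <- if (k < n - 1L) r < deadline else r <= deadline
    if (!readable) {
      status[k + 1L] <- "lost"
    } else {
      read_time[k + 1L] <- r
      il_ready <- r + ld$il_cost_us + jitter(ld$il_jitter_us)
      if (!closed) {
        status[k + 1L] <- "rtl-off"
      } else {
        if (!det$armed && r >= rearm_at) {
          detector_reset(det, armed = TRUE)
          win_start <- Inf
        }
        if (!det$armed && r >= win_start) {
          status[k + 1L] <- "protocol-window"
        } else if (rtl_ready > r) {
          status[k + 1L] <- "rtl-busy"
        } else {
          status[k + 1L] <- "analyzed"
          t_done <- r + ld$rtl_cost_us + jitter(ld$rtl_jitter_us)
          rtl_ready <- t_done
          ev <- detector_step(det, m, t_done)
          if (!is.null(ev)) {
            det$armed <- FALSE
            win_start <- ev$time_us
            det_t <- c(det_t, ev$time_us)
            det_k <- c(det_k, k)
            det_rv <- c(det_rv, ev$rel_variation)
            on_t <- ev$time_us + prot$pre_delay_us
            off_t <- on_t + prot$pulse_us
            rearm_at <- off_t + prot$post_delay_us
            stim_on <- c(stim_on, on_t)
            stim_off <- c(stim_off, off_t)
            stim_q <- sort(c(stim_q, on_t))
          }
        }
      }
    }
    k <- k + 1L
  }

  frames_df <- data.frame(
    frame_index = seq_len(n) - 1L,
    camera_timestamp_us = (seq_len(n) - 1L) * exposure,
    read_time_us = read_time,
    status = status,
    stringsAsFactors = FALSE
  )
  log <- structure(list(
    frames = frames_df,
    detections = data.frame(time_us = det_t, frame_index = det_k,
                            rel_variation = det_rv),
    stims = data.frame(on_us = stim_on, off_us = stim_off,
                       amplitude = rep(if (is.null(prot)) NA_real_ else
                                       prot$amplitude, length(stim_on))),
    produced = n,
    acquired = as.integer(sum(status != "lost")),
    lost = as.integer(sum(status == "lost")),
    analyzed = as.integer(sum(status == "analyzed")),
    skipped_protocol = as.integer(sum(status == "protocol-window")),
    skipped_busy = as.integer(sum(status == "rtl-busy")),
    mode = config$mode,
    exposure_us = exposure,
    duration_us = config$duration_us,
    config = config
  ), class = "session_log")
  structure(list(frames = frames, log = log), class = "vt_session")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> %s, %.3f s at %d us exposure\n", x$mode,
    x$duration_us / 1e6, as.integer(x$exposure_us)))
  cat(sprintf(
    "  frames: %d produced = %d acquired + %d lost\n",
    x$produced, x$acquired, x$lost))
  cat(sprintf(
    "  acquired: %d analyzed, %d protocol-window, %d rtl-busy, %d rtl-off\n",
    x$analyzed, x$skipped_protocol, x$skipped_busy,
    sum(x$frames$status == "rtl-off")))
  cat(sprintf("  events: %d detections, %d stimulations\n",
              nrow(x$detections), nrow(x$stims)))
  invisible(x)
}

#' Write a session log as CSV tables
#'
#' Emits `frames.csv` (per-frame records: index, camera timestamp, IL read
#' time, status) and `events.csv` (detections and stimulation pulses in one
#' long table: kind, time columns).
#'
#' @param log a `session_log`.
#' @param dir output directory.
#' @return Invisibly, the two file paths.
#' @export
write_session_log <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path(dir, "frames.csv")
  ep <- file.path(dir, "events.csv")
  utils::write.csv(log$frames, fp, row.names = FALSE)
  nd <- nrow(log$detections); ns <- nrow(log$stims)
  ev <- rbind(
    data.frame(kind = rep("detection", nd),
               time_us = log$detections$time_us,
               frame_index = log$detections$frame_index,
               value = log$detections$rel_variation),
    data.frame(kind = rep("stim_on", ns), time_us = log$stims$on_us,
               frame_index = rep(NA_integer_, ns),
               value = log$stims$amplitude),
    data.frame(kind = rep("stim_off", ns), time_us = log$stims$off_us,
               frame_index = rep(NA_integer_, ns),
               value = log$stims$amplitude)
  )
  ev <- ev[order(ev$time_us), ]
  utils::write.csv(ev, ep, row.names = FALSE)
  invisible(c(fp, ep))
}
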