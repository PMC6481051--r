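# Run-configuration files: a single YAML document with sections tissue,
# camera, detector, protocol, load, session. Every physical quantity
# carries its unit in the key name (_us, _mm, _ms, _fraction). Unknown keys
# are rejected so typos cannot silently fall back to defaults.

config_defaults <- function() {
  list(
    tissue = list(
      grid_rows = 128L, grid_cols = 128L, px_size_mm = 10 / 128,
      cv_mm_per_ms = 0.5, upstroke_ms = 2, apd_ms = 40, repol_ms = 20,
      refractory_ms = 70, f0_counts = 10000, sensitivity_fraction = 0.04,
      noise_sigma_px_fraction = 0.004
    ),
    camera = list(exposure_us = 2000L, rows = 128L, cols = 128L),
    detector = list(
      roi_x_mm = 4.85, roi_y_mm = 0.95, roi_w_mm = 0.3, roi_h_mm = 0.1,
      th_fraction = 0.01, buffer_len = 10L
    ),
    protocol = list(
      spot_center_x_mm = 5, spot_center_y_mm = 9, spot_diameter_mm = 1,
      pre_delay_us = 200000L, pulse_us = 5000L, post_delay_us = 5000L,
      illumination_intensity_mw_mm2 = 1, stim_intensity_mw_mm2 = 4
    ),
    load = list(il_cost_us = 0, rtl_cost_us = 0,
                il_jitter_us = 0, rtl_jitter_us = 0),
    session = list(mode = "closed-loop", duration_us = 10e6,
                   init_stim_us = 20000, seed = 1L, keep_frames = TRUE,
                   out_dir = "")
  )
}

merge_section <- function(section, user, defaults) {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop(sprintf("config section '%s' must be a mapping", section))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop(sprintf("unknown key '%s' in config section '%s'",
                 unknown[1L], section))
  utils::modifyList(defaults, user)
}

#' Read and validate a run-configuration file
#'
#' Parses a YAML run configuration (see [write_run_config()] for the
#' layout; any omitted key takes its default, which is the platform's
#' reference parameter set: 2 ms exposure, 1% threshold, 200/5/5 ms
#' protocol, 1 mm apex spot, 0.1 x 0.3 mm base ROI). Unknown keys are an
#' error naming the offending key. LED intensity fields are accepted and
#' logged but do not modulate the tissue model.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return A validated [run_config()] object.
#' @export
read_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  def <- config_defaults()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config section '%s'", unknown[1L]))
  cfg <- lapply(names(def), function(s) merge_section(s, raw[[s]], def[[s]]))
  names(cfg) <- names(def)

  tp <- with(cfg$tissue, tissue_params(
    grid_shape = c(grid_rows, grid_cols), px_size_mm = px_size_mm,
    cv_mm_ms = cv_mm_per_ms, upstroke_ms = upstroke_ms, apd_ms = apd_ms,
    repol_ms = repol_ms, refractory_ms = refractory_ms, f0 = f0_counts,
    sensitivity = sensitivity_fraction,
    noise_sigma_px = noise_sigma_px_fraction, seed = cfg$session$seed))
  cam <- with(cfg$camera, camera_config(exposure_us, c(rows, cols)))
  mode <- cfg$session$mode
  if (!mode %in% c("closed-loop", "free-run"))
    stop("session mode must be 'closed-loop' or 'free-run'")
  detc <- with(cfg$detector, detector_config(
    roi_from_mm(c(roi_x_mm, roi_y_mm), c(roi_w_mm, roi_h_mm), tp),
    th = th_fraction, buffer_len = buffer_len))
  prot <- with(cfg$protocol, stim_protocol(
    make_circular_mask(c(spot_center_x_mm, spot_center_y_mm),
                       spot_diameter_mm, tp),
    pre_delay_us = pre_delay_us, pulse_us = pulse_us,
    post_delay_us = post_delay_us, amplitude = stim_intensity_mw_mm2))
  ldm <- with(cfg$load, load_model(il_cost_us, rtl_cost_us,
                                   il_jitter_us, rtl_jitter_us))
  out <- run_config(tissue = tp, camera = cam, detector = detc,
                    protocol = prot, load = ldm, mode = mode,
                    duration_us = cfg$session$duration_us,
                    init_stim_us = if (is.null(cfg$session$init_stim_us) ||
                                       is.na(cfg$session$init_stim_us))
                                     NA_real_
                                   else cfg$session$init_stim_us,
                    seed = cfg$session$seed)
  out$raw <- cfg
  out$keep_frames <- isTRUE(cfg$session$keep_frames)
  out$out_dir <- cfg$session$out_dir
  out
}

#' Write a run configuration as YAML
#'
#' Writes the fully resolved key set, so the file re-parses to an
#' identical validated configuration (round-trip property).
#'
#' @param config a [run_config()] from [read_run_config()], or a raw
#'   section list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  raw <- if (inherits(config, "vt_config")) config$raw else config
  if (is.null(raw)) stop("config carries no raw key set to serialize")
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' The reference run configuration
#'
#' The parameter set of the platform's 3-minute stability demonstration:
#' closed-loop at 2 ms exposure, detection threshold 1% dF/F,
#' pre-activation delay 200 ms, pulse 5 ms, post-activation delay 5 ms,
#' a 1 mm circular stimulation spot at the apex and a 0.1 x 0.3 mm
#' detection ROI at the base.
#'
#' @param ... named overrides applied to config sections, e.g.
#'   `session = list(duration_us = 30e6)`.
#' @return A validated [run_config()] object.
#' @export
reference_config <- function(...) {
  over <- list(...)
  def <- config_defaults()
  bad <- setdiff(names(over), names(def))
  if (length(bad) > 0L) stop(sprintf("unknown config section '%s'", bad[1L]))
  for (s in names(over)) def[[s]] <- utils::modifyList(def[[s]], over[[s]])
  read_run_config(def)
}
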