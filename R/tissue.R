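#' Virtual cardiac tissue parameters
#'
#' Parameter set for the activation-time (eikonal-style) excitable-tissue
#' model that stands in for the optically mapped heart. Frames cover a
#' roughly 10 x 10 mm field of view at 128 x 128 px; voltage-sensitive-dye
#' (VSD) fluorescence *decreases* upon depolarization with fractional
#' amplitude `sensitivity`, and each pixel carries independent Gaussian
#' noise of standard deviation `noise_sigma_px * f0` counts.
#'
#' The action potential is a piecewise-linear template: a linear upstroke of
#' `upstroke_ms`, a plateau of `apd_ms`, and a linear repolarization ramp of
#' `repol_ms`. A pixel cannot re-activate until `refractory_ms` after its
#' last activation.
#'
#' @param grid_shape integer vector `(rows, cols)`; frame geometry.
#' @param px_size_mm pixel pitch in mm (default 10/128, i.e. a 10 mm field).
#' @param cv_mm_ms planar conduction velocity in mm/ms.
#' @param upstroke_ms,apd_ms,repol_ms action-potential phase durations (ms).
#' @param refractory_ms minimum interval between successive activations of
#'   one pixel (ms); must be at least `upstroke_ms + apd_ms`.
#' @param f0 resting fluorescence level in camera counts.
#' @param sensitivity fractional fluorescence drop at full depolarization
#'   (dF/F at v = 1); about 0.04 for di-4-ANBDQPQ-class dyes.
#' @param noise_sigma_px per-pixel additive noise standard deviation as a
#'   fraction of `f0`. The default 0.004 puts the shot noise of a few-pixel
#'   detection ROI mean near 0.2% dF/F.
#' @param seed integer seed used by [run_session()] for all randomness.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(grid_shape = c(128L, 128L),
                          px_size_mm = 10 / 128,
                          cv_mm_ms = 0.5,
                          upstroke_ms = 2,
                          apd_ms = 40,
                          repol_ms = 20,
                          refractory_ms = 70,
                          f0 = 10000,
                          sensitivity = 0.04,
                          noise_sigma_px = 0.004,
                          seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L))
  if (px_size_mm <= 0) stop("px_size_mm must be > 0")
  if (cv_mm_ms <= 0) stop("cv_mm_ms must be > 0")
  for (d in c(upstroke_ms, apd_ms, repol_ms, refractory_ms))
    if (!is.finite(d) || d <= 0) stop("all durations must be > 0")
  if (refractory_ms < upstroke_ms + apd_ms)
    stop("refractory_ms must be >= upstroke_ms + apd_ms")
  if (sensitivity <= 0 || sensitivity >= 1)
    stop("sensitivity must lie strictly in (0, 1)")
  if (noise_sigma_px < 0) stop("noise_sigma_px must be >= 0")
  if (f0 <= 0 || f0 * (1 + 5 * noise_sigma_px) > 65535)
    stop("f0 (plus 5 sigma of noise) must fit in 16 bits")
  structure(list(
    grid_shape = grid_shape, px_size_mm = px_size_mm, cv_mm_ms = cv_mm_ms,
    upstroke_ms = upstroke_ms, apd_ms = apd_ms, repol_ms = repol_ms,
    refractory_ms = refractory_ms, f0 = f0, sensitivity = sensitivity,
    noise_sigma_px = noise_sigma_px, seed = as.integer(seed)
  ), class = "tissue_params")
}

# Pixel-center coordinates (mm). Origin at the outer corner of pixel [1,1];
# x runs along columns (rightwards), y along rows (downwards).
pixel_centers <- function(params) {
  nr <- params$grid_shape[1L]; nc <- params$grid_shape[2L]
  px <- params$px_size_mm
  list(
    x = rep((seq_len(nc) - 0.5) * px, each = nr),
    y = rep((seq_len(nr) - 0.5) * px, times = nc)
  )
}

new_stim_mask <- function(pixels, descriptor) {
  if (!any(pixels))
    stop("empty stimulation mask: the stimulus cannot excite any tissue")
  structure(list(pixels = pixels, descriptor = descriptor,
                 cache = new.env(parent = emptyenv())),
            class = "stim_mask")
}

#' Circular photostimulation mask
#'
#' Builds the boolean pixel membership map of a circular light spot (as
#' projected by a DMD), e.g. the 1 mm spot used to pace the ventricular
#' apex. A pixel belongs to the mask iff its center lies strictly within
#' `diameter_mm / 2` of `center_mm`.
#'
#' @param center_mm numeric `(x, y)` center in mm.
#' @param diameter_mm spot diameter in mm.
#' @param params a [tissue_params()] object (grid geometry).
#' @return A `stim_mask` object: logical `rows x cols` matrix plus a
#'   descriptor recording the geometry.
#' @export
make_circular_mask <- function(center_mm, diameter_mm, params) {
  ctr <- pixel_centers(params)
  r <- diameter_mm / 2
  inside <- (ctr$x - center_mm[1L])^2 + (ctr$y - center_mm[2L])^2 < r^2
  pix <- matrix(inside, params$grid_shape[1L], params$grid_shape[2L])
  new_stim_mask(pix, list(shape = "circle", center_mm = center_mm,
                          diameter_mm = diameter_mm))
}

#' Rectangular mask
#'
#' Pixel membership for an axis-aligned rectangle given in mm; used both
#' for rectangular stimuli and to resolve detection ROIs specified in mm.
#' A pixel belongs iff its center lies in the half-open rectangle
#' `[x, x+w) x [y, y+h)`.
#'
#' @param corner_mm `(x, y)` of the top-left corner in mm.
#' @param size_mm `(w, h)` in mm.
#' @inheritParams make_circular_mask
#' @return A `stim_mask` object.
#' @export
make_rect_mask <- function(corner_mm, size_mm, params) {
  ctr <- pixel_centers(params)
  inside <- ctr$x >= corner_mm[1L] & ctr$x < corner_mm[1L] + size_mm[1L] &
            ctr$y >= corner_mm[2L] & ctr$y < corner_mm[2L] + size_mm[2L]
  pix <- matrix(inside, params$grid_shape[1L], params$grid_shape[2L])
  new_stim_mask(pix, list(shape = "rect", corner_mm = corner_mm,
                          size_mm = size_mm))
}

# Distance (mm) from every pixel center to the nearest mask pixel center,
# cached on the mask (reused for every full-mask stimulus and by
# predict_period). Brute force over mask members, chunked to bound memory.
mask_distance_mm <- function(mask, params) {
  if (!is.null(mask$cache$dist_mm)) return(mask$cache$dist_mm)
  ctr <- pixel_centers(params)
  idx <- which(mask$pixels)
  d2 <- rep(Inf, length(ctr$x))
  for (j in idx) {
    d2 <- pmin(d2, (ctr$x - ctr$x[j])^2 + (ctr$y - ctr$y[j])^2)
  }
  d <- sqrt(d2)
  mask$cache$dist_mm <- d
  d
}

#' Create a quiescent tissue state
#'
#' The state is a mutable environment holding, per pixel, the time of the
#' most recent activation (`-Inf` for never) and a time-sorted queue of
#' pending wavefront arrivals scheduled by earlier stimuli.
#'
#' @param params a [tissue_params()] object.
#' @return An environment of class `tissue_state`.
#' @export
tissue_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$n_px <- prod(params$grid_shape)
  st$last_act <- rep(-Inf, st$n_px)    # activation times, microseconds
  st$pend_t <- numeric(0)              # sorted pending arrival times (us)
  st$pend_px <- integer(0)
  st$clock_us <- 0
  class(st) <- "tissue_state"
  st
}

# Consume pending arrivals up to and including time t_us. An arrival takes
# effect only if the pixel is past its refractory period at arrival time;
# otherwise it is discarded.
advance_state <- function(state, t_us) {
  n <- length(state$pend_t)
  if (n > 0L && state$pend_t[1L] <= t_us) {
    refr_us <- state$params$refractory_ms * 1000
    hi <- findInterval(t_us, state$pend_t)
    px <- state$pend_px[seq_len(hi)]
    tt <- state$pend_t[seq_len(hi)]
    if (anyDuplicated(px)) {
      la <- state$last_act
      for (k in seq_len(hi)) {
        if (tt[k] - la[px[k]] > refr_us) la[px[k]] <- tt[k]
      }
      state$last_act <- la
    } else {
      ok <- tt - state$last_act[px] > refr_us
      state$last_act[px[ok]] <- tt[ok]
    }
    keep <- seq.int(hi + 1L, length.out = n - hi)
    state$pend_t <- state$pend_t[keep]
    state$pend_px <- state$pend_px[keep]
  }
  state$clock_us <- t_us
  invisible(state)
}

#' Apply a patterned light stimulus to the tissue
#'
#' Models a channelrhodopsin-activating light pulse: every masked pixel
#' past its refractory period activates at `t_us`, and a wavefront is
#' scheduled from the activated set — each remaining pixel receives an
#' arrival at `t_us + distance-to-nearest-source / cv`, which takes effect
#' only if that pixel is excitable when the front arrives.
#'
#' @param state a [tissue_state()] (mutated in place and returned).
#' @param mask a `stim_mask`.
#' @param t_us stimulus time in microseconds; must not precede the state
#'   clock.
#' @return The updated state, invisibly.
#' @export
apply_stimulus <- function(state, mask, t_us) {
  if (t_us < state$clock_us) stop("stimulus time precedes the tissue clock")
  advance_state(state, t_us)
  params <- state$params
  refr_us <- params$refractory_ms * 1000
  midx <- which(mask$pixels)
  act <- midx[t_us - state$last_act[midx] > refr_us]
  if (length(act) == 0L) return(invisible(state))
  state$last_act[act] <- t_us

  others <- setdiff(seq_len(state$n_px), act)
  if (length(others) == 0L) return(invisible(state))
  if (length(act) == length(midx)) {
    d <- mask_distance_mm(mask, params)        # cached field, 0 on the mask
    d_oth <- d[others]
  } else {
    ctr <- pixel_centers(params)
    d2 <- rep(Inf, length(others))
    for (j in act) {
      d2 <- pmin(d2, (ctr$x[others] - ctr$x[j])^2 +
                     (ctr$y[others] - ctr$y[j])^2)
    }
    d_oth <- sqrt(d2)
  }
  if (length(others) > 0L) {
    arr_t <- t_us + d_oth / params$cv_mm_ms * 1000
    all_t <- c(state$pend_t, arr_t)
    all_px <- c(state$pend_px, others)
    o <- order(all_t)
    state$pend_t <- all_t[o]
    state$pend_px <- all_px[o]
  }
  invisible(state)
}

#' Action-potential waveform template
#'
#' Normalized membrane potential as a function of time since activation:
#' 0 before activation, a linear 0 to 1 upstroke over `upstroke_ms`, a
#' plateau of 1 for `apd_ms`, a linear 1 to 0 ramp over `repol_ms`, then 0.
#'
#' @param tau_ms time since activation, ms (vectorized).
#' @param params a [tissue_params()] object.
#' @return Numeric vector of values in `[0, 1]`.
#' @export
ap_waveform <- function(tau_ms, params) {
  total <- params$upstroke_ms + params$apd_ms + params$repol_ms
  pmin(pmax(tau_ms, 0) / params$upstroke_ms, 1,
       pmax((total - tau_ms) / params$repol_ms, 0))
}

#' Render a fluorescence frame from the tissue state
#'
#' Per pixel, `F = f0 * (1 - sensitivity * v(t - last_activation))` plus
#' Gaussian noise of sd `noise_sigma_px * f0`, rounded half away from zero
#' and clipped to the 16-bit range. The dye signal is negative-going:
#' fluorescence at full depolarization is lower than rest by
#' `sensitivity * f0` before noise. Pending wavefront arrivals are consumed
#' up to `t_us` before rendering. Noise is drawn from R's global RNG, so
#' frame sequences are bit-reproducible for a fixed seed.
#'
#' @param state a [tissue_state()].
#' @param t_us frame (camera) time, microseconds.
#' @param pixels optional integer vector of pixel indices (column-major);
#'   when given, only those pixels are rendered and a vector is returned.
#' @return Integer `rows x cols` matrix (or vector for a pixel subset).
#' @export
render_frame <- function(state, t_us, pixels = NULL) {
  advance_state(state, t_us)
  params <- state$params
  la <- if (is.null(pixels)) state$last_act else state$last_act[pixels]
  v <- ap_waveform((t_us - la) / 1000, params)
  f <- params$f0 * (1 - params$sensitivity * v)
  if (params$noise_sigma_px > 0)
    f <- f + stats::rnorm(length(f), 0, params$noise_sigma_px * params$f0)
  out <- as.integer(floor(pmin(pmax(f, 0), 65535) + 0.5))
  if (is.null(pixels))
    out <- matrix(out, params$grid_shape[1L], params$grid_shape[2L])
  out
}
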