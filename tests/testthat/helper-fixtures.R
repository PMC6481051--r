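# Shared fixtures: small grids and short sessions keep unit tests quick;
# the reference geometry (128 x 128, 10 mm field) is used where the test
# is about the full-scale loop.

tiny_params <- function(...) {
  tissue_params(grid_shape = c(32L, 32L), px_size_mm = 10 / 32, ...)
}

# fast-recovering tissue used for short-period experiments
fast_tissue <- list(upstroke_ms = 2, apd_ms = 20, repol_ms = 10,
                    refractory_ms = 35)

# a short reference closed-loop run (seconds of simulated time)
short_cfg <- function(duration_us = 2e6, seed = 1L, keep_frames = FALSE,
                      noise = 0.004, ...) {
  reference_config(
    tissue = list(noise_sigma_px_fraction = noise),
    session = list(duration_us = duration_us, seed = seed,
                   keep_frames = keep_frames),
    ...
  )
}

# brute-force oracle: pixel centers within a circle / rectangle, by
# explicit per-pixel loop (independent of the implementation's vectorized
# geometry)
brute_circle_count <- function(center_mm, diameter_mm, params) {
  nr <- params$grid_shape[1L]; nc <- params$grid_shape[2L]
  px <- params$px_size_mm
  count <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    x <- (j - 0.5) * px; y <- (i - 0.5) * px
    if (sqrt((x - center_mm[1L])^2 + (y - center_mm[2L])^2) < diameter_mm / 2)
      count <- count + 1L
  }
  count
}

brute_rect_count <- function(corner_mm, size_mm, params) {
  nr <- params$grid_shape[1L]; nc <- params$grid_shape[2L]
  px <- params$px_size_mm
  count <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    x <- (j - 0.5) * px; y <- (i - 0.5) * px
    if (x >= corner_mm[1L] && x < corner_mm[1L] + size_mm[1L] &&
        y >= corner_mm[2L] && y < corner_mm[2L] + size_mm[2L])
      count <- count + 1L
  }
  count
}

# recount error rates directly from a per-frame record table
recount_rates <- function(frames_df, mode = "closed-loop") {
  produced <- nrow(frames_df)
  lost <- sum(frames_df$status == "lost")
  acquired <- produced - lost
  busy <- sum(frames_df$status == "rtl-busy")
  prot <- sum(frames_df$status == "protocol-window")
  list(il = lost / produced,
       rtl = if (acquired - prot > 0) busy / (acquired - prot) else 0)
}
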