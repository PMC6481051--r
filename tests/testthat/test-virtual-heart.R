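test_that("tissue parameter invariants are enforced", {
  expect_s3_class(tissue_params(), "tissue_params")
  expect_error(tissue_params(cv_mm_ms = 0), "cv")
  expect_error(tissue_params(refractory_ms = 10), "refractory")
  expect_error(tissue_params(sensitivity = 1.2), "sensitivity")
  expect_error(tissue_params(f0 = 70000), "16 bits")
})

test_that("circular mask matches a brute-force pixel-center scan", {
  params <- tissue_params()
  # degenerate geometry: zero diameter excites nothing
  expect_error(make_circular_mask(c(5, 5), 0, params), "empty")
  # circle covering the whole field selects every pixel
  m_all <- make_circular_mask(c(5, 5), 20, params)
  expect_equal(sum(m_all$pixels), 128L * 128L)
  # the 1 mm stimulation spot: membership equals the per-pixel oracle
  m1 <- make_circular_mask(c(5, 9), 1, params)
  expect_equal(sum(m1$pixels), brute_circle_count(c(5, 9), 1, params))
  expect_gt(sum(m1$pixels), 0)
  # and on an off-grid center
  m2 <- make_circular_mask(c(3.21, 4.87), 1, params)
  expect_equal(sum(m2$pixels), brute_circle_count(c(3.21, 4.87), 1, params))
})

test_that("rectangular mask uses half-open pixel-center membership", {
  params <- tissue_params()
  m_all <- make_rect_mask(c(0, 0), c(10, 10), params)
  expect_equal(sum(m_all$pixels), 128L * 128L)
  # the 0.1 x 0.3 mm detection-window geometry
  m <- make_rect_mask(c(4.85, 0.95), c(0.3, 0.1), params)
  expect_equal(sum(m$pixels), brute_rect_count(c(4.85, 0.95), c(0.3, 0.1),
                                               params))
  expect_error(make_rect_mask(c(20, 20), c(1, 1), params), "empty")
})

test_that("action-potential template is the piecewise-linear shape", {
  p <- tissue_params()
  expect_equal(ap_waveform(-1, p), 0)
  expect_equal(ap_waveform(0, p), 0)
  expect_equal(ap_waveform(p$upstroke_ms, p), 1)
  expect_equal(ap_waveform(p$upstroke_ms / 2, p), 0.5)
  expect_equal(ap_waveform(p$upstroke_ms + p$apd_ms, p), 1)
  expect_equal(ap_waveform(p$upstroke_ms + p$apd_ms + p$repol_ms / 2, p), 0.5)
  expect_equal(ap_waveform(p$upstroke_ms + p$apd_ms + p$repol_ms + 1, p), 0)
})

test_that("stimulus scheduling matches brute-force nearest-source arrival", {
  params <- tissue_params(noise_sigma_px = 0)
  st <- tissue_state(params)
  mask <- make_circular_mask(c(5, 9), 1, params)
  apply_stimulus(st, mask, 0)
  # ground truth by brute-force nearest-activated-source search
  idx <- which(mask$pixels)
  nr <- params$grid_shape[1L]
  px <- params$px_size_mm
  probe <- c(1L, 5000L, 9000L, 16384L)
  advance_t <- 40e3  # all arrivals well past by 40 ms at cv 0.5
  vtloop:::advance_state(st, advance_t)
  for (p in probe) {
    pi <- (p - 1L) %% nr + 1L; pj <- (p - 1L) %/% nr + 1L
    x <- (pj - 0.5) * px; y <- (pi - 0.5) * px
    d <- Inf
    for (q in idx) {
      qi <- (q - 1L) %% nr + 1L; qj <- (q - 1L) %/% nr + 1L
      d <- min(d, sqrt((x - (qj - 0.5) * px)^2 + (y - (qi - 0.5) * px)^2))
    }
    expect_equal(st$last_act[p], d / params$cv_mm_ms * 1000,
                 tolerance = 1e-12)
  }
  # a pixel 8 mm from the source activates 16 ms later at cv 0.5 mm/ms
  dists <- vtloop:::mask_distance_mm(mask, params)
  p8 <- which(abs(dists - 8) == min(abs(dists - 8)))[1L]
  expect_equal(st$last_act[p8] / 1000, dists[p8] / 0.5, tolerance = 1e-9)
})

test_that("refractory tissue ignores stimuli and discarded arrivals", {
  params <- tiny_params(noise_sigma_px = 0)
  st <- tissue_state(params)
  mask <- make_circular_mask(c(5, 5), 3, params)
  apply_stimulus(st, mask, 0)
  la <- st$last_act[which(mask$pixels)]
  # restimulating inside the refractory period changes nothing
  apply_stimulus(st, mask, 10e3)
  expect_equal(st$last_act[which(mask$pixels)], la)
  # full-field stimulus on quiescent tissue: everything fires, no arrivals
  st2 <- tissue_state(params)
  full <- make_rect_mask(c(0, 0), c(10, 10), params)
  apply_stimulus(st2, full, 5)
  expect_true(all(st2$last_act == 5))
  expect_length(st2$pend_t, 0)
})

test_that("no pixel ever re-activates within the refractory period", {
  params <- tiny_params(noise_sigma_px = 0)
  mask <- make_circular_mask(c(2, 2), 2, params)
  mask2 <- make_circular_mask(c(8, 8), 2, params)
  st <- tissue_state(params)
  # a deliberately aggressive schedule: re-stimulation faster than recovery
  times <- c(0, 15e3, 40e3, 71e3, 90e3, 140e3, 141e3)
  hist <- vector("list", st$n_px)
  last <- st$last_act
  for (k in seq_along(times)) {
    apply_stimulus(st, if (k %% 2) mask else mask2, times[k])
    vtloop:::advance_state(st, times[k])
    changed <- which(st$last_act != last)
    for (p in changed) hist[[p]] <- c(hist[[p]], st$last_act[p])
    last <- st$last_act
  }
  vtloop:::advance_state(st, 1e6)
  changed <- which(st$last_act != last)
  for (p in changed) hist[[p]] <- c(hist[[p]], st$last_act[p])
  gaps <- unlist(lapply(hist, function(h) if (length(h) > 1L) diff(h)))
  expect_true(all(gaps > params$refractory_ms * 1000))
})

test_that("rendered fluorescence is negative-going with exact amplitude", {
  params <- tissue_params(noise_sigma_px = 0)
  st <- tissue_state(params)
  # quiescent, noise-free: uniform resting level
  f_rest <- render_frame(st, 0)
  expect_true(all(f_rest == params$f0))
  # full depolarization: rest minus sensitivity * f0
  full <- make_rect_mask(c(0, 0), c(10, 10), params)
  apply_stimulus(st, full, 0)
  f_dep <- render_frame(st, params$upstroke_ms * 1000)
  expect_true(all(f_dep == round(params$f0 * (1 - params$sensitivity))))
  expect_lt(max(f_dep), min(f_rest))
})

test_that("seeded rendering is bit-reproducible", {
  params <- tiny_params()
  st <- tissue_state(params)
  set.seed(99); a <- render_frame(st, 1000)
  set.seed(99); b <- render_frame(st, 1000)
  expect_identical(a, b)
  expect_identical(storage.mode(a), "integer")
})

test_that("a point stimulus recovers the configured wave speed", {
  params <- tissue_params(noise_sigma_px = 0)
  st <- tissue_state(params)
  mask <- make_circular_mask(c(5, 5), 0.3, params)
  apply_stimulus(st, mask, 0)
  vtloop:::advance_state(st, 60e3)
  d <- vtloop:::mask_distance_mm(mask, params)
  act <- st$last_act
  ok <- is.finite(act) & act > 0
  fit <- stats::lm(d[ok] ~ I(act[ok] / 1000))
  slope_cv <- unname(stats::coef(fit)[2L])
  expect_lt(abs(slope_cv - params$cv_mm_ms) / params$cv_mm_ms, 0.02)
})
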