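test_that("free-run sessions acquire everything under zero load", {
  cfg <- reference_config(session = list(duration_us = 2e6,
                                         mode = "free-run",
                                         init_stim_us = NA))
  cfg$camera <- camera_config(1000L)
  log <- run_session(cfg, keep_frames = FALSE)$log
  expect_equal(log$produced, 2000L)
  expect_equal(log$lost, 0L)
  expect_equal(log$analyzed, 0L)          # RTL off
  expect_true(all(log$frames$status == "rtl-off"))
  expect_equal(nrow(log$detections), 0L)
})

test_that("quiescent noise-free closed-loop tissue yields no detections", {
  cfg <- reference_config(
    tissue = list(noise_sigma_px_fraction = 0),
    session = list(duration_us = 3e6, init_stim_us = NA))
  log <- run_session(cfg, keep_frames = FALSE)$log
  expect_equal(nrow(log$detections), 0L)
  expect_equal(log$analyzed, log$acquired)
})

test_that("the stimulation protocol follows the additive three-phase schedule", {
  cfg <- short_cfg(duration_us = 1.5e6, noise = 0)
  log <- run_session(cfg, keep_frames = FALSE)$log
  expect_gt(nrow(log$detections), 1L)
  prot <- cfg$protocol
  # pulse on at detection + pre_delay, off pulse_us later
  expect_equal(log$stims$on_us, log$detections$time_us + prot$pre_delay_us)
  expect_equal(log$stims$off_us, log$stims$on_us + prot$pulse_us)
  # detector stays quiet for the whole protocol window
  window <- prot$pre_delay_us + prot$pulse_us + prot$post_delay_us
  expect_true(all(diff(log$detections$time_us) >= window))
  # detections and stimulations alternate, starting with a detection
  ev <- rbind(data.frame(t = log$detections$time_us, kind = "d"),
              data.frame(t = log$stims$on_us, kind = "s"))
  ev <- ev[order(ev$t), ]
  expect_equal(ev$kind, rep(c("d", "s"), nrow(log$detections)))
})

test_that("re-arming is immediate when all protocol delays shrink to zero", {
  cfg <- reference_config(
    tissue = list(noise_sigma_px_fraction = 0),
    protocol = list(pre_delay_us = 0L, pulse_us = 1L, post_delay_us = 0L),
    session = list(duration_us = 3e5, init_stim_us = 10000,
                   keep_frames = FALSE))
  log <- run_session(cfg, keep_frames = FALSE)$log
  # re-armed 1 us after each event: no frame is ever skipped as
  # protocol-window (the next frame falls after the window)
  expect_equal(log$skipped_protocol, 0L)
  expect_gt(nrow(log$detections), 0L)
})

test_that("frame accounting is conserved under arbitrary load", {
  cfg <- short_cfg(duration_us = 3e6)
  cfg$load <- load_model(il_cost_us = 900, rtl_cost_us = 700,
                         il_jitter_us = 2500, rtl_jitter_us = 2500)
  log <- run_session(cfg, keep_frames = FALSE)$log
  st <- table(factor(log$frames$status,
                     c("analyzed", "protocol-window", "rtl-busy",
                       "rtl-off", "lost")))
  expect_equal(log$produced, log$acquired + log$lost)
  expect_equal(log$acquired,
               log$analyzed + log$skipped_protocol + log$skipped_busy +
                 sum(log$frames$status == "rtl-off"))
  expect_equal(sum(st), log$produced)   # each frame in exactly one class
  # reported rates equal brute-force recounts of the per-frame records
  rc <- recount_rates(log$frames)
  expect_identical(il_error_rate(log), rc$il)
  expect_identical(rtl_error_rate(log), rc$rtl)
})

test_that("costs below the exposure guarantee stable operation", {
  cfg <- short_cfg(duration_us = 4e6)
  cfg$load <- load_model(il_cost_us = 1500, rtl_cost_us = 1800)  # < 2000
  log <- run_session(cfg, keep_frames = FALSE)$log
  expect_equal(log$lost, 0L)
  expect_equal(log$skipped_busy, 0L)
})

test_that("frame loss responds monotonically to load and exposure", {
  base <- reference_config(session = list(duration_us = 2e6,
                                          mode = "free-run",
                                          init_stim_us = NA))
  loss_at <- function(exposure_us, il_cost_us) {
    cfg <- base
    cfg$camera <- camera_config(as.integer(exposure_us))
    cfg$load <- load_model(il_cost_us = il_cost_us)
    il_error_rate(run_session(cfg, keep_frames = FALSE)$log)
  }
  # increasing il_cost never decreases loss at fixed exposure
  losses_cost <- vapply(c(0, 500, 1000, 1500, 2500, 4000), loss_at,
                        numeric(1), exposure_us = 1000)
  expect_true(all(diff(losses_cost) >= 0))
  # increasing exposure never increases loss at fixed cost
  losses_exp <- vapply(c(500, 1000, 2000, 5000), function(e)
    loss_at(e, 1500), numeric(1))
  expect_true(all(diff(losses_exp) <= 0))
})

test_that("identical configuration and seed reproduce the session exactly", {
  cfg <- short_cfg(duration_us = 8e5, seed = 5L, keep_frames = TRUE)
  a <- run_session(cfg, keep_frames = TRUE)
  b <- run_session(cfg, keep_frames = TRUE)
  expect_identical(a$log$frames, b$log$frames)
  expect_identical(a$log$detections, b$log$detections)
  for (k in seq_along(a$frames))
    expect_identical(a$frames[[k]]$pixels, b$frames[[k]]$pixels)
})

test_that("closed-loop sessions sustain the predicted re-entry period", {
  cfg <- short_cfg(duration_us = 3e6, noise = 0)
  log <- run_session(cfg, keep_frames = FALSE)$log
  iv <- predict_period(cfg)
  cs <- cycle_stats(log$detections$time_us)
  expect_gte(cs$mean_period_us, iv[1])
  expect_lte(cs$mean_period_us, iv[2])
})
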