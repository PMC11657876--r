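fr <- 99.6
mk_time <- function(T_) (seq_len(T_) - 1) / fr

test_that("baseline_drift measures pre-stimulus window change, table convention", {
  tt <- mk_time(3000)
  flat <- rep(80, 3000)
  expect_equal(baseline_drift(flat, tt, 8), 0)
  # linear 5% decay across the pre-stimulus segment: windows sit at the ends,
  # expected value computed from the window centers (closed form)
  pre <- tt < 8
  y <- ifelse(pre, 80 * (1 - 0.05 * tt / 8), 80 * 0.95)
  got <- baseline_drift(y, tt, 8)
  n_pre <- sum(pre)
  ini <- mean(y[1:10]); fin <- mean(y[(n_pre - 9):n_pre])
  expect_equal(got, (fin - ini) / ini * 100)
  expect_lt(got, -4.5); expect_gt(got, -5.0)
  expect_error(baseline_drift(flat, tt, 0.1), "need at least")
  expect_error(baseline_drift(flat, tt, -3), "positive")
})

test_that("detect_onset finds a noiseless step to within one smoothing window", {
  tt <- mk_time(3000)
  y <- ifelse(tt >= 10, 120, 100)  # step 2 s after a stimulus at 8 s
  r <- detect_onset(y, tt, 8)
  expect_true(r$degenerate_baseline)
  expect_false(r$no_response)
  expect_lt(abs(r$onset_delay_s - 2), 25 / fr)
  # flat trace: no response
  rf <- detect_onset(rep(100, 3000), tt, 8)
  expect_true(rf$no_response)
  expect_true(is.na(rf$onset_delay_s))
})

test_that("onset and peak are offset-invariant and time-shift equivariant", {
  set.seed(25)
  tt <- mk_time(3000)
  y <- 100 + 0.05 * rnorm(3000)
  y <- y + 2 * pmin(pmax(tt - 11, 0), 3)  # ramp at 11 s, plateau at 14 s
  r1 <- detect_onset(y, tt, 8)
  r2 <- detect_onset(y + 500, tt, 8)
  expect_equal(r1$onset_delay_s, r2$onset_delay_s, tolerance = 1e-9)
  # shifting both time axis and stimulus leaves the delay unchanged up to
  # one frame (window boundaries are compared in absolute time)
  r3 <- detect_onset(y, tt + 5, 13)
  expect_lt(abs(r1$onset_delay_s - r3$onset_delay_s), 1 / fr)
  p1 <- time_to_peak(y, tt, r1$onset_time_s, 8)
  p2 <- time_to_peak(y + 500, tt, r1$onset_time_s, 8)
  expect_equal(p1$time_to_peak_s, p2$time_to_peak_s)
})

test_that("rise_rate is the least-squares slope and scales with gain", {
  tt <- mk_time(1000)
  y <- 40 + 1.25 * tt
  expect_lt(abs(rise_rate(y, tt, 2) - 1.25), 1e-9)
  expect_equal(rise_rate(rep(7, 1000), tt, 2), 0)
  expect_equal(rise_rate(3 * y, tt, 2), 3 * 1.25, tolerance = 1e-9)
  expect_error(rise_rate(y, tt, 9.99, fit_window_s = 0.001), "fewer than 3")
})

test_that("time_to_peak locates a triangular pulse and flags unpeaked traces", {
  tt <- mk_time(3000)
  y <- 100 + pmax(0, 4 - abs(tt - 12))  # peak at t = 12 s
  p <- time_to_peak(y, tt, onset_time_s = 9, stimulus_time_s = 8)
  expect_lt(abs((p$time_to_peak_s + 8) - 12), 2 * 25 / fr)
  expect_false(p$unpeaked)
  # monotone to the end: record end, flagged
  y2 <- 100 + tt
  p2 <- time_to_peak(y2, tt, 9, 8)
  expect_true(p2$unpeaked)
  expect_equal(p2$time_to_peak_s + 8, max(tt), tolerance = 25 / fr)
  # flat trace: unpeaked
  expect_true(time_to_peak(rep(5, 3000), tt, 9, 8)$unpeaked)
})

test_that("noiseless simulated responses are recovered to a frame interval", {
  cfg <- glucose_sim_config(
    n_cells = 3L, fov_shape = c(100L, 170L), cell_radius_px = c(12, 16),
    n_frames = 1500L, shot_noise = FALSE, read_noise_sd = 0,
    bleach_cell_sdlog = 0, bleach_rate_451 = 0, bleach_rate_560 = 0,
    perturbation_params = list(stimulus_time_s = 5, delay_range_s = c(1, 3),
                               pre_drift_percent = 0),
    seed = 26L)
  sim <- simulate_timelapse(cfg)
  tr <- extract_traces(sim_channel_stack(sim), sim$truth$label_mask)
  rep_ <- analyze_dynamics(tr, 5)
  r451 <- rep_[rep_$series == "i451", ]
  expect_equal(nrow(rep_), 9L)  # 3 cells x 3 series
  expect_true(all(abs(r451$onset_delay_s - sim$truth$true_delay_s) < 2 / fr))
  expect_true(all(abs(r451$rise_rate_au_per_s - sim$truth$true_rate_au_per_s) /
                    sim$truth$true_rate_au_per_s < 1e-3))
  expect_true(all(!r451$no_response))
  # the ORR series responds too (451 rises faster than 560 by construction)
  rorr <- rep_[rep_$series == "orr", ]
  expect_true(all(!rorr$no_response))
})

test_that("a stimulus-free record yields no-response flags everywhere", {
  cfg <- tiny_sim_config(n_frames = 1200L, frame_rate_hz = 99.6,
                         bleach_rate_451 = 0, bleach_rate_560 = 0, seed = 27L)
  sim <- simulate_timelapse(cfg)
  tr <- extract_traces(sim_channel_stack(sim), sim$truth$label_mask)
  rep_ <- analyze_dynamics(tr, 5)
  expect_true(all(rep_$no_response))
})
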