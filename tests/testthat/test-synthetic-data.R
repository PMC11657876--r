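test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_frames = 0), "n_frames")
  expect_error(simulation_config(nucleus_factor = 0), "nucleus_factor")
  expect_error(simulation_config(nucleus_factor = 1.2), "nucleus_factor")
  expect_error(simulation_config(base_intensity_451 = -5), "negative")
  expect_error(simulation_config(read_noise_sd = -1), "negative")
})

test_that("no sources means every pixel equals the background offset", {
  cfg <- simulation_config(n_cells = 0L, fov_shape = c(10L, 16L), n_frames = 3L,
                           shot_noise = FALSE, read_noise_sd = 0,
                           background_offset = 100)
  sim <- simulate_timelapse(cfg)
  expect_true(all(sim$stack == 100))
  expect_identical(dim(sim$stack), c(10L, 32L, 3L))
})

test_that("identical config and seed give bit-identical stacks", {
  cfg <- tiny_sim_config(seed = 9L)
  s1 <- simulate_timelapse(cfg)
  s2 <- simulate_timelapse(cfg)
  expect_identical(s1$stack, s2$stack)
  expect_identical(s1$truth$true_trace_451, s2$truth$true_trace_451)
  # a different seed changes the pixels
  s3 <- simulate_timelapse(tiny_sim_config(seed = 10L))
  expect_false(identical(s1$stack, s3$stack))
})

test_that("noiseless traces measured on ground-truth masks equal the truth", {
  cfg <- noiseless_sim_config(seed = 7L)
  sim <- simulate_timelapse(cfg)
  cs <- sim_channel_stack(sim)
  tr <- extract_traces(cs, sim$truth$label_mask)
  expect_equal(tr$mean_451, sim$truth$true_trace_451, tolerance = 1e-12)
  expect_equal(tr$mean_560, sim$truth$true_trace_560, tolerance = 1e-12)
})

test_that("zero bleach gives constant traces and zero percent change", {
  cfg <- noiseless_sim_config(bleach_rate_451 = 0, bleach_rate_560 = 0)
  sim <- simulate_timelapse(cfg)
  expect_equal(apply(sim$truth$true_trace_451, 1, stats::sd), rep(0, 3))
  expect_true(all(abs(sim$truth$true_bleach_percent$percent_eq2) < 1e-12))
})

test_that("noiseless monoexponential bleaching matches the windowed closed form", {
  # closed form computed here, independently of the generator's bookkeeping:
  # windows of I(t) = I0 exp(-k t) + offset at the first/last 10 frame times
  k <- 0.01
  cfg <- noiseless_sim_config(n_frames = 200L, frame_rate_hz = 99.4,
                              bleach_rate_451 = k, bleach_rate_560 = k / 2,
                              background_offset = 0)
  sim <- simulate_timelapse(cfg)
  tt <- (0:199) / 99.4
  i0 <- sim$truth$true_trace_451[, 1]
  w1 <- sapply(i0, function(a) mean(a * exp(-k * tt[1:10])))
  w2 <- sapply(i0, function(a) mean(a * exp(-k * tt[191:200])))
  expected <- (w1 - w2) / w1 * 100
  got <- subset(sim$truth$true_bleach_percent, metric == "i451")$percent_eq2
  expect_equal(got, unname(expected), tolerance = 1e-10)
  # and the pipeline measures the same thing on the noiseless stack
  tr <- extract_traces(sim_channel_stack(sim), sim$truth$label_mask)
  pb <- photobleach_report(tr)
  expect_equal(subset(pb, metric == "i451")$percent_eq2, unname(expected),
               tolerance = 1e-10)
})

test_that("expected intensity is exactly linear in illumination x exposure", {
  base <- noiseless_sim_config(background_offset = 0, bleach_rate_451 = 0,
                               bleach_rate_560 = 0, n_frames = 1L,
                               frame_rate_hz = 40)
  s1 <- simulate_timelapse(base)
  s2 <- simulate_timelapse(noiseless_sim_config(
    background_offset = 0, bleach_rate_451 = 0, bleach_rate_560 = 0,
    n_frames = 1L, frame_rate_hz = 40, exposure_ms = 20))
  expect_equal(s2$stack, 2 * s1$stack, tolerance = 1e-12)
  s3 <- simulate_timelapse(noiseless_sim_config(
    background_offset = 0, bleach_rate_451 = 0, bleach_rate_560 = 0,
    n_frames = 1L, frame_rate_hz = 40, illumination_mw = 2 * 4.14))
  expect_equal(s3$stack, 2 * s1$stack, tolerance = 1e-12)
})

test_that("shot noise is Poisson: per-pixel variance tracks the mean", {
  # one giant uniform cell so >= 1e4 pixels share a known rate
  cfg <- simulation_config(n_cells = 1L, fov_shape = c(150L, 150L),
                           cell_radius_px = c(68, 68), nucleus_factor = 1,
                           mito_density = 0L, base_intensity_451 = 1000,
                           background_offset = 0, read_noise_sd = 0,
                           bleach_rate_451 = 0, bleach_rate_560 = 0,
                           n_frames = 2L, frame_rate_hz = 50, seed = 12L)
  sim <- simulate_timelapse(cfg)
  px <- sim$stack[, 1:150, 1][sim$truth$label_mask > 0 &
                                sim$truth$base_451 == 1000]
  expect_gt(length(px), 1e4)
  expect_lt(abs(stats::var(px) / mean(px) - 1), 0.1)
})

test_that("cell phantoms have the stated compartment structure", {
  set.seed(21)
  # mito_density 0, nucleus_factor 1: a uniform ellipse
  ph <- make_cell_phantom(c(10, 12), c(5, 6), base_451 = 50, base_560 = 20,
                          nucleus_factor = 1, mito_density = 0L)
  expect_equal(unique(ph$t451[ph$mask]), 50)
  expect_true(all(ph$t451[!ph$mask] == 0))

  # nucleus dimming ratio is exactly nucleus_factor
  ph2 <- make_cell_phantom(c(10, 12), c(5, 6), nucleus_factor = 0.5,
                           mito_density = 0L)
  cyto <- ph2$mask & !ph2$nucleus
  expect_equal(mean(ph2$t451[ph2$nucleus]) / mean(ph2$t451[cyto]), 0.5)

  # puncta: the configured number of seeds is drawn (counted at fixed seed)
  set.seed(33)
  ph3 <- make_cell_phantom(c(12, 12), c(5, 5), mito_density = 7L,
                           mito_factor = 2)
  expect_true(sum(ph3$mito) >= 7)        # seeds dilated to crosses
  expect_true(all(ph3$t451[ph3$mito] == 2 * 32))
  expect_true(all(!(ph3$mito & ph3$nucleus)))  # puncta confined to cytoplasm

  expect_error(make_cell_phantom(c(5, 5), c(6, 6)), "smaller")
})

test_that("impossible placements fail with an explicit error", {
  expect_error(
    simulate_timelapse(simulation_config(n_cells = 40L, fov_shape = c(60L, 60L),
                                         n_frames = 1L, seed = 1L)),
    "40 non-overlapping cells in a 60 x 60")
})

test_that("glucose response: ramp slope, onset frame, and edge cases", {
  fr <- 99.6
  tt <- (0:2999) / fr
  traces <- matrix(50, 2, 3000)
  # rate 0 leaves the trace unchanged
  r0 <- apply_glucose_response(traces, tt, 8, delay_s = 1, rate_au_per_s = 0)
  expect_identical(r0$traces, traces)
  # noiseless slope between onset and plateau equals the rate to 1e-9
  r <- apply_glucose_response(traces, tt, 8, delay_s = 8, rate_au_per_s = 1,
                              plateau_multiplier = 1.2)
  y <- r$traces[1, ]
  onset <- 16; plateau_t <- onset + 0.2 * 50 / 1
  win <- which(tt > onset + 1e-9 & tt < plateau_t - 1e-9)
  slopes <- diff(y[win]) / diff(tt[win])
  expect_true(all(abs(slopes - 1) < 1e-9))
  expect_equal(max(y), 60)  # plateau at 1.2 x 50
  # first modified frame: the first timestamp strictly after stimulus+delay
  first_changed <- which(y > 50)[1]
  expect_identical(first_changed, which(tt > 16)[1])
  expect_error(apply_glucose_response(traces, tt, 8, -1, 1), "negative delay")
  expect_error(apply_glucose_response(traces, tt, 8, 1, -2), "negative rise")
  expect_error(apply_glucose_response(traces, tt, 40, 1, 1), "outside")
})

test_that("glucose-mode ground truth is self-consistent without bleaching", {
  cfg <- glucose_sim_config(
    n_cells = 2L, fov_shape = c(80L, 150L), cell_radius_px = c(12, 16),
    n_frames = 1500L, shot_noise = FALSE, read_noise_sd = 0,
    bleach_rate_451 = 0, bleach_rate_560 = 0, bleach_cell_sdlog = 0,
    perturbation_params = list(stimulus_time_s = 5, delay_range_s = c(1, 2),
                               pre_drift_percent = 0),
    seed = 6L)
  sim <- simulate_timelapse(cfg)
  # with no bleach and no drift the net noiseless slope equals the drawn rate
  expect_equal(sim$truth$true_rate_au_per_s,
               sim$truth$true_rate_drawn_au_per_s, tolerance = 1e-6)
})
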