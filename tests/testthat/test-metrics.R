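test_that("compute_orr handles the canonical values and rejects bad input", {
  expect_equal(compute_orr(100, 100), 0.5)
  expect_equal(compute_orr(100, 0), 1.0)
  expect_equal(compute_orr(3, 1), 0.75)
  expect_error(compute_orr(0, 0), "undefined")
  expect_error(compute_orr(-1, 5), "non-negative")
})

test_that("ORR algebraic properties hold over randomized inputs", {
  set.seed(19)
  a <- stats::runif(500, 1e-6, 1e4)
  b <- stats::runif(500, 1e-6, 1e4)
  r <- compute_orr(a, b)
  expect_true(all(r > 0 & r < 1))
  expect_equal(compute_orr(a, a), rep(0.5, 500))
  # gain invariance (exact up to floating-point rounding)
  g <- stats::runif(500, 0.01, 100)
  expect_equal(compute_orr(g * a, g * b), compute_orr(a, b), tolerance = 1e-12)
  # strict monotonicity in the 451 intensity at fixed 560
  expect_true(all(compute_orr(a * 1.01, b) > r))
})

test_that("orr_image is the ratio of masked means and matches a pixel loop", {
  a <- matrix(100, 8, 8); b <- matrix(100, 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[2:5, 3:6] <- TRUE
  expect_equal(orr_image(a, b, mask)$orr, 0.5)
  expect_error(orr_image(a, b, matrix(FALSE, 8, 8)), "empty mask")

  set.seed(20)
  a <- matrix(rpois(900, 80), 30, 30)
  b <- matrix(rpois(900, 40), 30, 30)
  mask <- matrix(stats::runif(900) < 0.4, 30, 30)
  got <- orr_image(a, b, mask)
  # brute-force loop oracle
  sa <- 0; sb <- 0; n <- 0
  for (i in 1:30) for (j in 1:30) if (mask[i, j]) {
    sa <- sa + a[i, j]; sb <- sb + b[i, j]; n <- n + 1
  }
  expect_equal(got$mean_451, sa / n)
  expect_equal(got$orr, (sa / n) / (sa / n + sb / n))
  expect_equal(got$n_pixels, n)
})

test_that("percent_change conventions are exact mirrors and validate input", {
  expect_equal(percent_change(100, 90, "eq2"), 10)
  expect_equal(percent_change(100, 90, "table"), -10)
  set.seed(21)
  ini <- stats::runif(200, 1, 100); fin <- stats::runif(200, 0, 120)
  expect_equal(percent_change(ini, fin, "table"), -percent_change(ini, fin, "eq2"))
  expect_error(percent_change(0, 5), "positive")
  # any strictly decreasing positive trace bleaches (> 0) under eq2
  tr <- sort(stats::runif(40, 10, 50), decreasing = TRUE)
  wm <- function(x) mean(x)
  expect_gt(percent_change(mean(tr[1:10]), mean(tr[31:40]), "eq2"), 0)
})

test_that("extract_traces equals a per-frame brute-force loop", {
  cfg <- tiny_sim_config(n_frames = 6L, seed = 22L)
  sim <- simulate_timelapse(cfg)
  cs <- sim_channel_stack(sim)
  tr <- extract_traces(cs, sim$truth$label_mask)
  for (i in seq_along(tr$cell_ids)) {
    for (t in 1:6) {
      expect_equal(tr$mean_451[i, t],
                   mean(cs$data_451[, , t][sim$truth$label_mask == i]))
      expect_equal(tr$mean_560[i, t],
                   mean(cs$data_560[, , t][sim$truth$label_mask == i]))
    }
  }
  # single-pixel ROI: the trace is that pixel's time series
  lab1 <- matrix(0L, dim(cs)[1], dim(cs)[2])
  lab1[10, 10] <- 1L
  tr1 <- extract_traces(cs, lab1)
  expect_equal(tr1$mean_451[1, ], cs$data_451[10, 10, ])
})

test_that("photobleach_report windows, conventions and errors", {
  meta <- acquisition_meta(4.14, 10, 99.4)
  T_ <- 60
  mk_traces <- function(y451, y560) {
    structure(list(mean_451 = matrix(y451, 1), mean_560 = matrix(y560, 1),
                   time_s = (seq_len(T_) - 1) / 99.4, cell_ids = 1L,
                   n_pixels = 100L), class = "cell_traces")
  }
  # constant traces: 0% for every metric
  tr <- mk_traces(rep(120, T_), rep(40, T_))
  pb <- photobleach_report(tr)
  expect_equal(pb$percent_eq2, rep(0, 3))
  expect_equal(pb$initial_window_mean[pb$metric == "orr"], 0.75)
  # window means are exactly the first/last 10-frame averages
  y <- 100 + seq_len(T_)
  pb2 <- photobleach_report(mk_traces(y, rep(50, T_)))
  expect_equal(pb2$initial_window_mean[pb2$metric == "i451"], mean(y[1:10]))
  expect_equal(pb2$final_window_mean[pb2$metric == "i451"], mean(y[51:60]))
  expect_equal(pb2$percent_table, -pb2$percent_eq2)
  # too-short trace names the required length
  short <- mk_traces(rep(1, T_), rep(1, T_))
  short$mean_451 <- short$mean_451[, 1:15, drop = FALSE]
  short$mean_560 <- short$mean_560[, 1:15, drop = FALSE]
  expect_error(photobleach_report(short), "at least 20 frames")
})

test_that("compute_snr definitions, invariances and oracle", {
  img <- matrix(0, 20, 20)
  sig <- matrix(FALSE, 20, 20); sig[5:10, 5:10] <- TRUE
  bg <- !sig
  set.seed(23)
  img[bg] <- rep(c(3, 7), length.out = sum(bg))  # mean 5, sd ~2
  img[sig] <- 105
  r <- compute_snr(img, sig, bg)
  expect_equal(r$snr, (105 - 5) / stats::sd(img[bg]))
  # contrast SNR is offset-invariant
  r2 <- compute_snr(img + 1000, sig, bg)
  expect_equal(r2$snr, r$snr)
  # ratio definition differs exactly by the background mean term
  r3 <- compute_snr(img, sig, bg, definition = "ratio")
  expect_equal(r3$snr, 105 / r$background_sd)

  # Poisson background oracle: direct formula on the same pixels
  img4 <- matrix(rpois(400, 100), 20, 20)
  img4[sig] <- img4[sig] + 500
  o_mean <- mean(img4[bg]); o_sd <- stats::sd(img4[bg])
  expect_equal(compute_snr(img4, sig, bg)$snr,
               (mean(img4[sig]) - o_mean) / o_sd)

  expect_error(compute_snr(img, sig, sig), "disjoint")
  flat <- matrix(5, 20, 20)
  expect_error(compute_snr(flat, sig, bg), "zero variance")
})

test_that("snr_timepoints reports start/end contrast SNR per channel", {
  cfg <- tiny_sim_config(n_frames = 30L, seed = 24L)
  sim <- simulate_timelapse(cfg)
  cs <- sim_channel_stack(sim)
  snr <- snr_timepoints(cs, sim$truth$label_mask)
  expect_equal(snr$channel, c("451", "560"))
  expect_true(all(snr$start_snr > 0))
  expect_equal(snr$percent_change,
               (snr$end_snr - snr$start_snr) / snr$start_snr * 100)
})
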