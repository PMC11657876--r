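# brute-force Otsu oracle: try every candidate split of the sorted unique
# values and maximize the between-class variance directly
otsu_oracle <- function(x) {
  v <- as.vector(x)
  u <- sort(unique(v))
  if (length(u) < 2) return(NA_real_)
  best <- -Inf; thr <- NA_real_
  for (i in seq_len(length(u) - 1)) {
    cand <- (u[i] + u[i + 1]) / 2
    lo <- v[v <= cand]; hi <- v[v > cand]
    bc <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; thr <- cand }
  }
  thr
}

test_that("otsu separates a bimodal image and matches the exhaustive oracle", {
  img <- matrix(c(rep(10, 50), rep(100, 50)), 10, 10)
  m <- threshold_background(img, "otsu")
  expect_equal(sum(m), 50)
  expect_true(all(img[m] == 100))
  thr <- attr(m, "threshold")
  expect_true(thr > 10 && thr < 100)

  set.seed(13)
  for (i in 1:20) {
    x <- matrix(sample(0:255, 400, replace = TRUE,
                       prob = stats::runif(256)^2), 20, 20)
    expect_equal(otsu_threshold(x), otsu_oracle(x))
  }
})

test_that("fixed and percentile thresholds behave as specified", {
  img <- matrix(stats::runif(100, 1, 5), 10, 10)
  expect_true(all(threshold_background(img, "fixed", value = 0)))
  # values 1..100, one pixel each, p = 50 keeps exactly 50 pixels
  img2 <- matrix(1:100, 10, 10)
  m <- threshold_background(img2, "percentile", p = 50)
  expect_equal(sum(m), 50)
  expect_true(all(img2[m] > 50))
  expect_error(threshold_background(img2, "percentile", p = 150), "\\[0, 100\\]")
  expect_error(threshold_background(img2, "fixed"), "value")
})

test_that("raising a fixed threshold never grows the mask (monotonicity)", {
  set.seed(14)
  img <- matrix(rpois(600, 40), 20, 30)
  thr <- sort(stats::runif(8, 20, 60))
  masks <- lapply(thr, function(v) threshold_background(img, "fixed", value = v))
  for (i in seq_len(length(thr) - 1)) {
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
  }
})

test_that("a constant image yields an empty mask with a warning, not a crash", {
  img <- matrix(7, 5, 5)
  expect_warning(m <- threshold_background(img, "otsu"), "constant image")
  expect_false(any(m))
  expect_true(attr(m, "degenerate"))
})

test_that("segment_cells labels, fills holes, and filters small components", {
  img <- two_blob_image()
  seg <- segment_cells(img, threshold_background(img, "fixed", value = 50),
                       min_area = 20)
  expect_equal(seg$n_cells, 2L)
  # scan order: the blob whose first pixel comes first in column-major order
  expect_equal(sort(unique(as.vector(seg$labels))), 0:2)

  # empty mask: zero cells, no error
  seg0 <- segment_cells(img, matrix(FALSE, 40, 60))
  expect_equal(seg0$n_cells, 0L)

  # a speck below min_area is removed
  img2 <- img; img2[20, 2] <- 500
  seg2 <- segment_cells(img2, threshold_background(img2, "fixed", value = 50),
                        min_area = 20)
  expect_equal(seg2$n_cells, 2L)

  # holes (a dim nucleus) are absorbed into the cell ROI when filling is on
  img3 <- matrix(0, 20, 20)
  img3[5:15, 5:15] <- 100
  img3[9:11, 9:11] <- 0       # "nucleus" below threshold
  mask3 <- threshold_background(img3, "fixed", value = 50)
  segf <- segment_cells(img3, mask3, min_area = 10, fill_holes = TRUE)
  expect_true(all(segf$labels[9:11, 9:11] == 1L))
  segn <- segment_cells(img3, mask3, min_area = 10, fill_holes = FALSE)
  expect_true(all(segn$labels[9:11, 9:11] == 0L))
})

test_that("segmentation recovers simulated phantoms", {
  # noiseless: exactly n_cells labels, pixel-perfect against ground truth
  cfg <- noiseless_sim_config(n_frames = 1L, seed = 15L)
  sim <- simulate_timelapse(cfg)
  cs <- sim_channel_stack(sim)
  avg <- cs$data_451[, , 1]
  seg <- segment_cells(avg, threshold_background(avg))
  expect_equal(seg$n_cells, cfg$n_cells)
  m <- match_rois(sim$truth$label_mask, seg$labels)
  expect_true(all(m$jaccard == 1))

  # with default noise on: all cells found, Jaccard >= 0.9
  cfgn <- tiny_sim_config(n_frames = 20L, seed = 16L)
  simn <- simulate_timelapse(cfgn)
  csn <- sim_channel_stack(simn)
  avgn <- rowMeans(csn$data_451, dims = 2)
  segn <- segment_cells(avgn, threshold_background(avgn))
  expect_equal(segn$n_cells, cfgn$n_cells)
  mn <- match_rois(simn$truth$label_mask, segn$labels)
  expect_true(all(mn$jaccard >= 0.9))
})

test_that("propagate_rois keeps static memberships and validates shapes", {
  cfg <- noiseless_sim_config(n_frames = 4L, seed = 17L)
  sim <- simulate_timelapse(cfg)
  cs <- sim_channel_stack(sim)
  rois <- propagate_rois(sim$truth$label_mask, cs)
  expect_equal(rois$n_frames, 4L)
  expect_equal(length(rois$pixels), 3L)
  expect_equal(rois$n_pixels, tabulate(sim$truth$label_mask))
  bad <- matrix(0L, 3, 3)
  expect_error(propagate_rois(bad, cs), "does not match")

  # T = 1 stack: per-frame means equal the frame itself under each ROI
  cfg1 <- noiseless_sim_config(n_frames = 1L, seed = 18L)
  sim1 <- simulate_timelapse(cfg1)
  cs1 <- sim_channel_stack(sim1)
  tr1 <- extract_traces(cs1, sim1$truth$label_mask)
  f <- cs1$data_451[, , 1]
  for (i in 1:3)
    expect_equal(tr1$mean_451[i, 1], mean(f[sim1$truth$label_mask == i]))
})
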