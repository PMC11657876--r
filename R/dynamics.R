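# Stimulus-response kinetics of per-cell intensity traces: pre-stimulus
# baseline drift, onset delay after the stimulus, linear rise rate, and
# time-to-peak. All estimators work on a centered moving-average smooth so
# they carry no phase lag, and all are invariant to adding a constant to
# the trace and equivariant under time shifts.

baseline_stats <- function(trace, time_s, stimulus_time_s, baseline_window_s = 2) {
  pre <- which(time_s < stimulus_time_s & time_s >= stimulus_time_s - baseline_window_s)
  if (length(pre) < 5L)
    stop("pre-stimulus segment too short to estimate a baseline", call. = FALSE)
  tt <- time_s[pre]; yy <- trace[pre]
  # detrend linearly so pre-stimulus drift inflates neither level nor sd;
  # the level is the fit evaluated at the stimulus time
  fit <- stats::lm.fit(cbind(1, tt - stimulus_time_s), yy)
  list(level = unname(fit$coefficients[1]),
       sd = stats::sd(fit$residuals),
       n = length(pre))
}

#' Pre-stimulus baseline drift
#'
#' Percent change (table convention: negative = decrease) between the mean
#' of the first `n_window` frames of the record and the mean of the last
#' `n_window` frames strictly before the stimulus.
#'
#' @param trace numeric vector of per-frame means.
#' @param time_s frame timestamps.
#' @param stimulus_time_s stimulus time (must be > 0 and inside the record).
#' @param n_window frames per window (default 10).
#' @return percent change.
#' @export
baseline_drift <- function(trace, time_s, stimulus_time_s, n_window = 10L) {
  if (stimulus_time_s <= 0 || stimulus_time_s > max(time_s))
    stop("stimulus_time_s must be positive and within the record", call. = FALSE)
  pre <- which(time_s < stimulus_time_s)
  if (length(pre) < 2L * n_window)
    stop(sprintf("pre-stimulus segment has %d frames; need at least %d (2 x n_window)",
                 length(pre), 2L * n_window), call. = FALSE)
  ini <- mean(trace[seq_len(n_window)])
  fin <- mean(trace[pre[(length(pre) - n_window + 1L):length(pre)]])
  percent_change(ini, fin, "table")
}

#' Detect the response onset after a stimulus
#'
#' Finds the first time at or after the stimulus where the smoothed trace
#' exceeds `baseline level + k_sd * baseline sd` for `m_consecutive`
#' consecutive frames. The baseline level and sd come from a linear fit over
#' the `baseline_window_s` seconds before the stimulus (evaluated at the
#' stimulus time, residual sd), so pre-stimulus drift biases neither. The
#' raw crossing time is biased late by roughly `k_sd * sd / slope`, so the
#' estimate is refined by back-extrapolating a local linear fit of the rise
#' to the baseline level. For a noiseless trace (zero baseline sd) the
#' criterion degrades to "any sustained increase" and is flagged.
#'
#' @param trace,time_s per-frame means and timestamps.
#' @param stimulus_time_s stimulus time.
#' @param k_sd threshold in baseline sds (default 3).
#' @param m_consecutive frames the threshold must be held (default 50,
#'   ~0.5 s at 99.6 Hz -- twice the smoothing window, so a single smoothed
#'   noise excursion cannot sustain a false detection).
#' @param smooth_window centered moving-average width in frames (default 25).
#' @param baseline_window_s seconds of pre-stimulus data used for the
#'   baseline fit (default 2).
#' @param refine_window_s seconds of rise used for the back-extrapolation
#'   (default 1).
#' @return list: `onset_delay_s` (NA if no response), `onset_time_s`,
#'   `threshold`, `baseline_level`, `baseline_sd`, `no_response`,
#'   `degenerate_baseline`.
#' @export
detect_onset <- function(trace, time_s, stimulus_time_s, k_sd = 3,
                         m_consecutive = 50L, smooth_window = 25L,
                         baseline_window_s = 2, refine_window_s = 1) {
  s <- moving_average(trace, smooth_window)
  bl <- baseline_stats(s, time_s, stimulus_time_s, baseline_window_s)
  degenerate <- bl$sd <= .Machine$double.eps^0.5 * max(abs(bl$level), 1)
  eps <- if (degenerate) .Machine$double.eps^0.5 * max(abs(bl$level), 1) else 0
  threshold <- bl$level + k_sd * bl$sd + eps
  post <- which(time_s >= stimulus_time_s)
  exceed <- s[post] > threshold
  run <- rle(exceed)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values & run$lengths >= m_consecutive)
  if (length(hit) == 0L) {
    return(list(onset_delay_s = NA_real_, onset_time_s = NA_real_,
                threshold = threshold, baseline_level = bl$level,
                baseline_sd = bl$sd, no_response = TRUE,
                degenerate_baseline = degenerate))
  }
  i0 <- post[starts[hit[1]]]
  t0 <- time_s[i0]
  # two-line changepoint refinement: intersect a local pre-onset baseline
  # line (fitted between the stimulus and just before the crossing, so that
  # slow post-stimulus decay such as continued photobleaching is tracked)
  # with a line fitted to the rise
  line_fit <- function(idx) {
    tt <- time_s[idx] - t0; yy <- s[idx]
    sl <- sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
    c(intercept = mean(yy) - sl * mean(tt), slope = sl)
  }
  win_all <- which(time_s >= t0 & time_s <= t0 + refine_window_s)
  # skip one smoothing window after the crossing (the smoothed kink is
  # convexly blended there and would bias the fitted rise line), and stop at
  # the running maximum (a step response plateaus inside the window and
  # fitting past the plateau would flatten the rise line)
  dt <- if (length(time_s) > 1L) time_s[2] - time_s[1] else 0
  win <- win_all[time_s[win_all] >= t0 + smooth_window * dt]
  if (length(win) >= 3L) win <- win[seq_len(which.max(s[win]))]
  if (length(win) < 3L) {
    win <- win_all
    if (length(win) >= 3L) win <- win[seq_len(which.max(s[win]))]
  }
  base_win <- which(time_s >= stimulus_time_s & time_s <= t0 - 0.5)
  onset_t <- t0
  if (length(win) >= 3L) {
    rise <- line_fit(win)
    base <- if (length(base_win) >= 10L) line_fit(base_win)
            else c(intercept = bl$level, slope = 0)
    if (is.finite(rise["slope"]) && rise["slope"] > base["slope"]) {
      dt <- (base["intercept"] - rise["intercept"]) /
        (rise["slope"] - base["slope"])
      onset_t <- t0 + unname(dt)
    }
  }
  # the crossing can precede the true kink (centered smoothing) or follow it
  # (threshold height), so allow the intersection to land anywhere between
  # the stimulus and the end of the rise-fit window
  onset_t <- min(max(onset_t, stimulus_time_s), t0 + refine_window_s)
  list(onset_delay_s = onset_t - stimulus_time_s, onset_time_s = onset_t,
       threshold = threshold, baseline_level = bl$level, baseline_sd = bl$sd,
       no_response = FALSE, degenerate_baseline = degenerate)
}

#' Initial rise rate after onset
#'
#' Least-squares slope of intensity versus time over
#' `[onset, onset + fit_window_s]`, in a.u. per second.
#'
#' @param trace,time_s per-frame means and timestamps.
#' @param onset_time_s response onset (from [detect_onset()]).
#' @param fit_window_s fit window length in seconds (default 2).
#' @return slope in a.u./s.
#' @export
rise_rate <- function(trace, time_s, onset_time_s, fit_window_s = 2) {
  win <- which(time_s >= onset_time_s & time_s <= onset_time_s + fit_window_s)
  if (length(win) < 3L)
    stop("fewer than 3 samples in the rise-rate fit window", call. = FALSE)
  tt <- time_s[win]; yy <- trace[win]
  sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
}

#' Time to peak intensity
#'
#' Time of the maximum of the smoothed post-onset trace, reported relative
#' to the stimulus. A trace still rising at the end of the record reports
#' the record end and is flagged `unpeaked` (the flag is also set when the
#' post-onset trace never exceeds its starting point).
#'
#' @param trace,time_s per-frame means and timestamps.
#' @param onset_time_s response onset.
#' @param stimulus_time_s reference time for the result (defaults to the
#'   onset if omitted).
#' @param smooth_window centered moving-average width in frames.
#' @return list: `time_to_peak_s`, `peak_value`, `unpeaked`.
#' @export
time_to_peak <- function(trace, time_s, onset_time_s,
                         stimulus_time_s = onset_time_s, smooth_window = 25L) {
  s <- moving_average(trace, smooth_window)
  post <- which(time_s >= onset_time_s)
  if (length(post) == 0L) stop("onset lies after the record end", call. = FALSE)
  k <- post[which.max(s[post])]
  flat <- max(s[post]) <= s[post[1]]
  unpeaked <- flat || k >= post[length(post)] - 1L
  if (flat) k <- post[length(post)]
  list(time_to_peak_s = time_s[k] - stimulus_time_s,
       peak_value = s[k], unpeaked = unpeaked)
}

#' Per-cell stimulus-response kinetics report
#'
#' Runs [baseline_drift()], [detect_onset()], [rise_rate()] and
#' [time_to_peak()] on the 451-nm, 560-nm and ORR series of every cell.
#' The ORR series is computed per frame from the smoothed channel means
#' (smooth-then-ratio; frame-level ratios of low counts amplify noise) --
#' set `smooth_ratio = FALSE` for raw per-frame ratios. Onsets are detected
#' per series; rise rate and time-to-peak use each series' own onset.
#'
#' @param traces a [extract_traces()] result.
#' @param stimulus_time_s stimulus time.
#' @param k_sd,m_consecutive,smooth_window,fit_window_s estimator settings,
#'   see the individual functions.
#' @param smooth_ratio smooth channel means before forming the ORR series.
#' @return data.frame (class `dynamics_report`): one row per cell x series
#'   with `baseline_drift_percent`, `onset_delay_s`, `rise_rate_au_per_s`,
#'   `time_to_peak_s`, `peak_value`, `no_response`, `unpeaked`.
#' @export
analyze_dynamics <- function(traces, stimulus_time_s, k_sd = 3,
                             m_consecutive = 50L, smooth_window = 25L,
                             fit_window_s = 2, smooth_ratio = TRUE) {
  stopifnot(inherits(traces, "cell_traces"))
  time_s <- traces$time_s
  n <- length(traces$cell_ids)
  out <- list()
  for (i in seq_len(n)) {
    t451 <- traces$mean_451[i, ]
    t560 <- traces$mean_560[i, ]
    orr <- if (smooth_ratio) {
      s451 <- moving_average(t451, smooth_window)
      s560 <- moving_average(t560, smooth_window)
      s451 / (s451 + s560)
    } else t451 / (t451 + t560)
    for (nm in c("i451", "i560", "orr")) {
      y <- switch(nm, i451 = t451, i560 = t560, orr = orr)
      drift <- baseline_drift(y, time_s, stimulus_time_s)
      on <- detect_onset(y, time_s, stimulus_time_s, k_sd = k_sd,
                         m_consecutive = m_consecutive,
                         smooth_window = smooth_window)
      rr <- NA_real_; ttp <- NA_real_; pk <- NA_real_; unpeaked <- NA
      if (!on$no_response) {
        rr <- rise_rate(y, time_s, on$onset_time_s, fit_window_s)
        tp <- time_to_peak(y, time_s, on$onset_time_s, stimulus_time_s,
                           smooth_window)
        ttp <- tp$time_to_peak_s; pk <- tp$peak_value; unpeaked <- tp$unpeaked
      }
      out[[length(out) + 1L]] <- data.frame(
        cell_id = traces$cell_ids[i], series = nm,
        baseline_drift_percent = drift,
        onset_delay_s = on$onset_delay_s,
        rise_rate_au_per_s = rr,
        time_to_peak_s = ttp, peak_value = pk,
        no_response = on$no_response, unpeaked = unpeaked,
        degenerate_baseline = on$degenerate_baseline)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("dynamics_report", "data.frame")
  res
}
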