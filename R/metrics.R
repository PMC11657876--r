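# Core quantities: the optical redox ratio 451/(451+560), first/last-window
# photobleaching percent change, contrast SNR, and per-cell trace extraction.

#' Optical redox ratio
#'
#' `ORR = I451 / (I451 + I560)` of two mean intensities. Lies in (0, 1) for
#' positive inputs, equals 0.5 for equal channels, is strictly increasing in
#' the 451-nm intensity, and is invariant to a common gain. Vectorized.
#'
#' @param mean_451,mean_560 non-negative mean intensities (a.u.); their sum
#'   must be positive.
#' @return the ratio.
#' @examples
#' compute_orr(100, 100)  # 0.5
#' compute_orr(3, 1)      # 0.75
#' @export
compute_orr <- function(mean_451, mean_560) {
  if (any(mean_451 < 0) || any(mean_560 < 0))
    stop("intensities must be non-negative", call. = FALSE)
  s <- mean_451 + mean_560
  if (any(s == 0))
    stop("ORR undefined: both channel intensities are zero", call. = FALSE)
  mean_451 / s
}

#' Image-level optical redox ratio
#'
#' Ratio of the masked channel means (means first, then the ratio -- not the
#' mean of pixelwise ratios): the two channel means are computed over the
#' same pixel set, then combined with [compute_orr()].
#'
#' @param img_451,img_560 equally sized matrices.
#' @param mask logical matrix selecting the pixels to average (must select
#'   at least one pixel).
#' @param bg_451,bg_560 per-channel background levels subtracted from the
#'   masked means before forming the ratio (default 0: raw means). Supply
#'   the camera offset / background estimate when the signal does not
#'   dominate it; negative differences are floored at 0.
#' @return list with `orr`, `mean_451`, `mean_560` (background-subtracted),
#'   `n_pixels`.
#' @export
orr_image <- function(img_451, img_560, mask, bg_451 = 0, bg_560 = 0) {
  stopifnot(all(dim(img_451) == dim(img_560)), all(dim(mask) == dim(img_451)))
  if (!any(mask)) stop("empty mask: no pixels to average", call. = FALSE)
  m451 <- max(mean(img_451[mask]) - bg_451, 0)
  m560 <- max(mean(img_560[mask]) - bg_560, 0)
  list(orr = compute_orr(m451, m560), mean_451 = m451, mean_560 = m560,
       n_pixels = sum(mask))
}

#' Pixelwise ORR map (visualization only)
#'
#' Per-pixel `I451 / (I451 + I560)`; pixels with zero sum become `NA`.
#' Quantitative comparisons should use [orr_image()] -- ratios of low-count
#' single pixels are noise-amplifying.
#' @inheritParams orr_image
#' @export
orr_map <- function(img_451, img_560) {
  s <- img_451 + img_560
  out <- img_451 / s
  out[s == 0] <- NA_real_
  out
}

#' Windowed percent change
#'
#' Percent change between an initial and a final window mean, under either
#' sign convention: `"eq2"` is `(initial - final) / initial * 100` (positive
#' means signal was lost, i.e. photobleaching), `"table"` is
#' `(final - initial) / initial * 100` (positive means signal increased).
#' The two differ only by sign. Values are returned at full precision;
#' reports round to 1 decimal.
#'
#' @param initial,final window means; `initial` must be positive.
#' @param convention `"eq2"` or `"table"`.
#' @return percent change (vectorized).
#' @export
percent_change <- function(initial, final, convention = c("eq2", "table")) {
  convention <- match.arg(convention)
  if (any(initial <= 0))
    stop("initial window mean must be positive", call. = FALSE)
  pc <- (initial - final) / initial * 100
  if (convention == "table") -pc else pc
}

#' Extract per-cell mean-intensity traces
#'
#' For every labeled ROI, computes the mean intensity over the ROI pixels on
#' each frame of both channels (the same pixel set in both). ROIs are static
#' across frames. Labels with zero pixels are excluded with a warning.
#'
#' @param channel_stack a [channel_stack()].
#' @param label_mask a [segment_cells()] result or bare integer label matrix.
#' @return a `cell_traces` object: list with `mean_451`, `mean_560`
#'   (cells x frames matrices), `time_s`, `cell_ids`, `n_pixels`.
#' @export
extract_traces <- function(channel_stack, label_mask) {
  rois <- propagate_rois(label_mask, channel_stack)
  if (length(rois$cell_ids) == 0L)
    stop("label mask contains no cells", call. = FALSE)
  empty <- rois$n_pixels == 0L
  if (any(empty)) {
    warning("excluding zero-pixel label(s): ",
            paste(rois$cell_ids[empty], collapse = ", "))
    rois$pixels <- rois$pixels[!empty]
    rois$cell_ids <- rois$cell_ids[!empty]
    rois$n_pixels <- rois$n_pixels[!empty]
  }
  n <- length(rois$cell_ids)
  T_ <- dim(channel_stack$data_451)[3]
  px <- unlist(rois$pixels)
  grp <- rep.int(seq_len(n), rois$n_pixels)
  m451 <- matrix(0, n, T_); m560 <- matrix(0, n, T_)
  for (t in seq_len(T_)) {
    f451 <- channel_stack$data_451[, , t]
    f560 <- channel_stack$data_560[, , t]
    sums <- rowsum(cbind(f451[px], f560[px]), grp)
    m451[, t] <- sums[, 1] / rois$n_pixels
    m560[, t] <- sums[, 2] / rois$n_pixels
  }
  structure(list(mean_451 = m451, mean_560 = m560,
                 time_s = channel_stack$time_s,
                 cell_ids = rois$cell_ids, n_pixels = rois$n_pixels),
            class = "cell_traces")
}

#' @export
print.cell_traces <- function(x, ...) {
  cat(sprintf("cell_traces: %d cell(s) x %d frame(s), %.2f s span\n",
              length(x$cell_ids), ncol(x$mean_451), max(x$time_s)))
  invisible(x)
}

#' @export
as.data.frame.cell_traces <- function(x, ...) {
  n <- length(x$cell_ids); T_ <- ncol(x$mean_451)
  data.frame(cell_id = rep(x$cell_ids, each = T_),
             time_s = rep(x$time_s, n),
             mean_451 = as.vector(t(x$mean_451)),
             mean_560 = as.vector(t(x$mean_560)))
}

window_means <- function(series, n_window) {
  T_ <- length(series)
  list(initial = mean(series[seq_len(n_window)]),
       final = mean(series[(T_ - n_window + 1L):T_]))
}

#' Photobleaching report
#'
#' For each cell, averages the first and last `n_window` frames of the
#' 451-nm, 560-nm and per-frame-ORR series and reports the percent change
#' under both sign conventions (see [percent_change()]). The ORR series is
#' computed per frame from the two channel means, then windowed.
#'
#' @param traces a [extract_traces()] result.
#' @param n_window frames per window (default 10).
#' @return data.frame (class `photobleach_report`) with one row per
#'   cell x metric: `cell_id`, `metric` (`i451`, `i560`, `orr`),
#'   `initial_window_mean`, `final_window_mean`, `percent_eq2`,
#'   `percent_table`, `n_window`.
#' @export
photobleach_report <- function(traces, n_window = 10L) {
  stopifnot(inherits(traces, "cell_traces"))
  T_ <- ncol(traces$mean_451)
  if (T_ < 2L * n_window)
    stop(sprintf("trace length %d is too short: need at least %d frames (2 x n_window)",
                 T_, 2L * n_window), call. = FALSE)
  n <- length(traces$cell_ids)
  orr <- traces$mean_451 / (traces$mean_451 + traces$mean_560)
  series <- list(i451 = traces$mean_451, i560 = traces$mean_560, orr = orr)
  rows <- lapply(names(series), function(nm) {
    s <- series[[nm]]
    ini <- rowMeans(s[, seq_len(n_window), drop = FALSE])
    fin <- rowMeans(s[, (T_ - n_window + 1L):T_, drop = FALSE])
    data.frame(cell_id = traces$cell_ids, metric = nm,
               initial_window_mean = ini, final_window_mean = fin,
               percent_eq2 = percent_change(ini, fin, "eq2"),
               percent_table = percent_change(ini, fin, "table"),
               n_window = n_window)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("photobleach_report", "data.frame")
  out
}

#' Contrast signal-to-noise ratio
#'
#' Default (`"contrast"`) definition:
#' `(mean(signal) - mean(background)) / sd(background)`; the `"ratio"`
#' alternative drops the background subtraction. The definition is recorded
#' in the result because the reference procedure reports SNR without a
#' formula. The contrast form is invariant to a constant offset.
#'
#' @param image numeric matrix.
#' @param signal_mask,background_mask disjoint, nonempty logical masks.
#' @param definition `"contrast"` or `"ratio"`.
#' @return list (class `snr_report`): `snr`, `signal_mean`,
#'   `background_mean`, `background_sd`, `definition`.
#' @export
compute_snr <- function(image, signal_mask, background_mask,
                        definition = c("contrast", "ratio")) {
  definition <- match.arg(definition)
  stopifnot(all(dim(signal_mask) == dim(image)),
            all(dim(background_mask) == dim(image)))
  if (!any(signal_mask) || !any(background_mask))
    stop("signal and background masks must be nonempty", call. = FALSE)
  if (any(signal_mask & background_mask))
    stop("signal and background masks must be disjoint", call. = FALSE)
  sm <- mean(image[signal_mask])
  bm <- mean(image[background_mask])
  bs <- stats::sd(image[background_mask])
  if (!is.finite(bs) || bs == 0)
    stop("background has zero variance: SNR undefined", call. = FALSE)
  snr <- switch(definition, contrast = (sm - bm) / bs, ratio = sm / bs)
  structure(list(snr = snr, signal_mean = sm, background_mean = bm,
                 background_sd = bs, definition = definition),
            class = "snr_report")
}

#' Start/end SNR of a time-lapse stack
#'
#' Computes the contrast SNR per channel on the time-averaged first
#' `n_window` and last `n_window` frames (start vs end of the record) plus
#' the percent change between them, table convention.
#'
#' @param channel_stack a [channel_stack()].
#' @param label_mask cell labels; signal = labeled pixels, background =
#'   unlabeled pixels.
#' @param n_window frames averaged per time point.
#' @param definition see [compute_snr()].
#' @return data.frame with one row per channel: `channel`, `start_snr`,
#'   `end_snr`, `percent_change` (1-dp rounded columns `*_1dp` included).
#' @export
snr_timepoints <- function(channel_stack, label_mask, n_window = 10L,
                           definition = "contrast") {
  labs <- if (inherits(label_mask, "label_mask")) label_mask$labels else label_mask
  sig <- labs > 0L
  bg <- !sig
  T_ <- dim(channel_stack$data_451)[3]
  stopifnot(T_ >= 2L * n_window)
  first <- seq_len(n_window); last <- (T_ - n_window + 1L):T_
  one <- function(data) {
    img_start <- rowMeans(data[, , first, drop = FALSE], dims = 2L)
    img_end <- rowMeans(data[, , last, drop = FALSE], dims = 2L)
    s <- compute_snr(img_start, sig, bg, definition)$snr
    e <- compute_snr(img_end, sig, bg, definition)$snr
    c(start = s, end = e)
  }
  r451 <- one(channel_stack$data_451)
  r560 <- one(channel_stack$data_560)
  out <- data.frame(channel = c("451", "560"),
                    start_snr = c(r451["start"], r560["start"]),
                    end_snr = c(r451["end"], r560["end"]))
  out$percent_change <- percent_change(out$start_snr, out$end_snr, "table")
  out$start_snr_1dp <- round1(out$start_snr)
  out$end_snr_1dp <- round1(out$end_snr)
  out$percent_change_1dp <- round1(out$percent_change)
  out
}
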