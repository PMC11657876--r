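#' Acquisition metadata for a split-frame stack
#'
#' Bundles the camera/illumination settings that every downstream
#' quantity depends on. The frame interval must be able to contain the
#' exposure (`frame_rate_hz * exposure_ms <= 1000`, within 1%).
#'
#' @param illumination_mw illumination power at the objective focal plane (mW).
#' @param exposure_ms camera integration time per frame (ms).
#' @param frame_rate_hz acquisition frame rate (Hz).
#' @param pixel_size_um physical pixel size in the sample plane (micrometers).
#' @param layout which half of each frame carries the 451-nm channel:
#'   `"left451"` (default; transmitted path of the image splitter) or
#'   `"right451"`.
#' @param bit_depth camera bit depth (8 or 16).
#' @return an `acquisition_meta` object (a validated list).
#' @export
acquisition_meta <- function(illumination_mw, exposure_ms, frame_rate_hz,
                             pixel_size_um = 0.65,
                             layout = c("left451", "right451"),
                             bit_depth = 16L) {
  layout <- match.arg(layout)
  for (nm in c("illumination_mw", "exposure_ms", "frame_rate_hz", "pixel_size_um")) {
    stopifnot_scalar_number(get(nm), nm)
    if (get(nm) <= 0) stop("`", nm, "` must be positive", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  if (frame_rate_hz * exposure_ms > 1000 * 1.01) {
    stop(sprintf(
      "exposure (%g ms) exceeds the frame interval at %g Hz (frame_rate_hz * exposure_ms = %g > 1000)",
      exposure_ms, frame_rate_hz, frame_rate_hz * exposure_ms), call. = FALSE)
  }
  structure(list(illumination_mw = illumination_mw, exposure_ms = exposure_ms,
                 frame_rate_hz = frame_rate_hz, pixel_size_um = pixel_size_um,
                 layout = layout, bit_depth = as.integer(bit_depth)),
            class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf("acquisition_meta: %.2f mW, %g ms exposure, %.1f Hz, %g um/px, layout %s, %d-bit\n",
              x$illumination_mw, x$exposure_ms, x$frame_rate_hz,
              x$pixel_size_um, x$layout, x$bit_depth))
  invisible(x)
}

meta_to_json <- function(meta) {
  jsonlite::toJSON(unclass(meta), auto_unbox = TRUE, digits = NA)
}

meta_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  acquisition_meta(x$illumination_mw, x$exposure_ms, x$frame_rate_hz,
                   x$pixel_size_um, x$layout, x$bit_depth)
}

#' Split a dual-emission frame into its two channel images
#'
#' Each acquired frame holds the 451-nm and 560-nm images of the same field
#' of view side by side. `split_frame` cuts the frame at the vertical
#' midline and assigns the halves according to `layout`;
#' `compose_frame` is its inverse.
#'
#' @param frame `H x W` matrix with even `W`.
#' @param layout `"left451"` or `"right451"`.
#' @return list with elements `img_451` and `img_560`, each `H x W/2`.
#' @examples
#' f <- cbind(matrix(10, 4, 3), matrix(20, 4, 3))
#' split_frame(f)$img_451[1, 1]  # 10
#' @export
split_frame <- function(frame, layout = c("left451", "right451")) {
  layout <- match.arg(layout)
  stopifnot(is.matrix(frame))
  W <- ncol(frame)
  if (W %% 2L != 0L)
    stop("frame width (", W, ") is odd; cannot split into equal halves", call. = FALSE)
  left <- frame[, seq_len(W / 2L), drop = FALSE]
  right <- frame[, (W / 2L + 1L):W, drop = FALSE]
  if (layout == "left451") list(img_451 = left, img_560 = right)
  else list(img_451 = right, img_560 = left)
}

#' @rdname split_frame
#' @param img_451,img_560 equally sized channel images.
#' @export
compose_frame <- function(img_451, img_560, layout = c("left451", "right451")) {
  layout <- match.arg(layout)
  stopifnot(all(dim(img_451) == dim(img_560)))
  if (layout == "left451") cbind(img_451, img_560) else cbind(img_560, img_451)
}

#' Register the two channel halves by integer-pixel cross-correlation
#'
#' The image splitter aligns the two halves optically, but a residual offset
#' of a few pixels can survive. This finds the integer shift of the 560-nm
#' image relative to the 451-nm image that maximizes the normalized
#' cross-correlation over the overlap, searching all shifts within
#' `max_shift`, and returns the 560-nm image translated back into alignment
#' (vacated pixels filled with `fill`). Ties are broken toward the smallest
#' shift, so identical images return (0, 0). No interpolation is performed:
#' downstream ratio metrics must not see resampled intensities.
#'
#' @param img_451,img_560 equally sized matrices.
#' @param max_shift maximum |dy|, |dx| searched (default 10).
#' @param fill value for pixels exposed by the alignment translation.
#' @return list with `shift` (c(dy, dx): displacement of the 560 half),
#'   `aligned_560`, `peak_ncc`, and `low_correlation` (TRUE when the best
#'   normalized correlation is below 0.2, e.g. for structure-free images).
#' @export
register_channels <- function(img_451, img_560, max_shift = 10L, fill = 0) {
  stopifnot(is.matrix(img_451), all(dim(img_451) == dim(img_560)))
  max_shift <- as.integer(max_shift)
  if (max_shift < 0L) stop("max_shift must be >= 0", call. = FALSE)
  H <- nrow(img_451); W <- ncol(img_451)
  if (max_shift >= H || max_shift >= W)
    stop("max_shift (", max_shift, ") must be smaller than the image extent",
         call. = FALSE)
  shifts <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  # visit small shifts first so ties resolve toward zero displacement
  shifts <- shifts[order(abs(shifts$dy) + abs(shifts$dx), abs(shifts$dy)), ]
  best <- -Inf; best_shift <- c(0L, 0L)
  for (i in seq_len(nrow(shifts))) {
    dy <- shifts$dy[i]; dx <- shifts$dx[i]
    r0 <- max(1L, 1L - dy); r1 <- min(H, H - dy)
    c0 <- max(1L, 1L - dx); c1 <- min(W, W - dx)
    a <- as.vector(img_451[r0:r1, c0:c1])
    b <- as.vector(img_560[(r0 + dy):(r1 + dy), (c0 + dx):(c1 + dx)])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    cc <- stats::cor(a, b)
    if (cc > best + 1e-12) { best <- cc; best_shift <- c(dy, dx) }
  }
  if (!is.finite(best)) { best <- 0; best_shift <- c(0L, 0L) }
  list(shift = as.integer(best_shift),
       aligned_560 = translate_img(img_560, -best_shift[1], -best_shift[2], fill),
       peak_ncc = best,
       low_correlation = best < 0.2)
}

#' Registered per-channel stack on a shared timebase
#'
#' Container pairing the 451-nm and 560-nm `H x W x T` arrays with their
#' acquisition metadata. Timestamps are `t = frame_index / frame_rate_hz`
#' with the first frame at t = 0.
#'
#' @param data_451,data_560 `H x W x T` arrays (a matrix is treated as T = 1).
#' @param meta [acquisition_meta()].
#' @param registration_shift integer `c(dy, dx)` that was applied to the 560
#'   half during registration (bookkeeping only).
#' @return a `channel_stack` object.
#' @export
channel_stack <- function(data_451, data_560, meta, registration_shift = c(0L, 0L)) {
  if (is.matrix(data_451)) dim(data_451) <- c(dim(data_451), 1L)
  if (is.matrix(data_560)) dim(data_560) <- c(dim(data_560), 1L)
  stopifnot(length(dim(data_451)) == 3L, all(dim(data_451) == dim(data_560)),
            inherits(meta, "acquisition_meta"))
  if (min(data_451, na.rm = TRUE) < 0 || min(data_560, na.rm = TRUE) < 0)
    stop("intensities must be non-negative", call. = FALSE)
  T_ <- dim(data_451)[3]
  structure(list(data_451 = data_451, data_560 = data_560,
                 time_s = (seq_len(T_) - 1) / meta$frame_rate_hz,
                 meta = meta,
                 registration_shift = as.integer(registration_shift)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$data_451)
  cat(sprintf("channel_stack: %d frame(s) of %d x %d per channel, %.2f s span\n",
              d[3], d[1], d[2], x$time_s[d[3]]))
  print(x$meta)
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$data_451)

#' Read / write a split-frame acquisition
#'
#' `write_stack` stores a raw split-frame stack (or a [channel_stack()],
#' which is recomposed per its layout) as a multi-page grayscale TIFF with
#' the acquisition metadata embedded as JSON in the ImageDescription tag.
#' `read_stack` reads it back; metadata may alternatively be supplied
#' explicitly (overriding the tag) for files produced elsewhere.
#'
#' @param path TIFF path.
#' @param meta optional [acquisition_meta()]; required if the file carries
#'   no embedded metadata.
#' @return `read_stack`: list with `frames` (`H x W x T` array), `meta`,
#'   `bits`.
#' @export
read_stack <- function(path, meta = NULL) {
  tf <- read_tiff_stack(path)
  if (is.null(meta)) {
    if (is.null(tf$description))
      stop("no acquisition metadata: file has no embedded description; pass `meta`",
           call. = FALSE)
    meta <- meta_from_json(tf$description)
  }
  list(frames = tf$frames, meta = meta, bits = tf$bits)
}

#' @rdname read_stack
#' @param x split-frame array (`H x 2W x T`) or a `channel_stack`.
#' @export
write_stack <- function(x, path, meta = NULL) {
  if (inherits(x, "channel_stack")) {
    meta <- x$meta
    T_ <- dim(x$data_451)[3]
    frames <- array(0, dim = c(dim(x$data_451)[1], 2L * dim(x$data_451)[2], T_))
    for (t in seq_len(T_)) {
      frames[, , t] <- compose_frame(x$data_451[, , t], x$data_560[, , t], meta$layout)
    }
    x <- frames
  }
  desc <- if (!is.null(meta)) meta_to_json(meta) else NULL
  bits <- if (!is.null(meta)) meta$bit_depth else 16L
  write_tiff_stack(x, path, bits = bits, description = desc)
}

#' Split a raw frame stack into a registered channel stack
#'
#' Applies [split_frame()] to every frame, optionally estimates the residual
#' channel offset on the time-averaged images with [register_channels()] and
#' applies it to every 560-nm frame.
#'
#' @param frames `H x 2W x T` array (or matrix for T = 1).
#' @param meta [acquisition_meta()].
#' @param register estimate and undo the 560-nm offset (default FALSE).
#' @param max_shift search radius for registration.
#' @return a [channel_stack()].
#' @export
split_stack <- function(frames, meta, register = FALSE, max_shift = 10L) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  T_ <- dim(frames)[3]
  halves <- split_frame(frames[, , 1], meta$layout)
  H <- nrow(halves$img_451); W <- ncol(halves$img_451)
  proto <- if (is.integer(frames)) 0L else 0
  d451 <- array(proto, dim = c(H, W, T_)); d560 <- array(proto, dim = c(H, W, T_))
  for (t in seq_len(T_)) {
    h <- split_frame(frames[, , t], meta$layout)
    d451[, , t] <- h$img_451; d560[, , t] <- h$img_560
  }
  shift <- c(0L, 0L)
  if (register) {
    avg451 <- rowMeans(d451, dims = 2L)
    avg560 <- rowMeans(d560, dims = 2L)
    reg <- register_channels(avg451, avg560, max_shift = max_shift)
    shift <- reg$shift
    if (any(shift != 0L)) {
      fill <- stats::median(d560[, , 1])
      for (t in seq_len(T_)) {
        d560[, , t] <- translate_img(d560[, , t], -shift[1], -shift[2], fill)
      }
    }
  }
  channel_stack(d451, d560, meta, registration_shift = shift)
}

#' @rdname read_stack
#' @param register,max_shift see [split_stack()].
#' @export
load_channel_stack <- function(path, meta = NULL, register = FALSE, max_shift = 10L) {
  st <- read_stack(path, meta)
  split_stack(st$frames, st$meta, register = register, max_shift = max_shift)
}
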