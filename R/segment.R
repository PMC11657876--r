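# Thresholding and ROI machinery. The reference procedure sets a manual
# threshold by eye to drop background (and optionally nucleus) pixels and
# traces one ROI per cell on the 451-nm channel; here both steps are
# reproducible: automatic thresholds, connected-component cell labels with
# filled holes, and static ROIs shared by both channels and all frames.

#' Otsu's threshold
#'
#' Exact maximization of the between-class variance over all candidate
#' splits of the observed values (no histogram binning), so it agrees with a
#' brute-force search on any input. Returns the midpoint between the two
#' classes; `NA` for constant images.
#'
#' @param x numeric vector or matrix.
#' @return threshold value, or `NA_real_` if the input is constant.
#' @export
otsu_threshold <- function(x) {
  v <- sort(as.vector(x))
  u <- unique(v)
  if (length(u) < 2L) return(NA_real_)
  counts <- tabulate(match(v, u))
  n <- length(v)
  m <- length(u)
  cw <- cumsum(counts)
  cs <- cumsum(counts * u)
  w0 <- cw[-m] / n
  mu0 <- cs[-m] / cw[-m]
  mu1 <- (cs[m] - cs[-m]) / (n - cw[-m])
  bc <- w0 * (1 - w0) * (mu0 - mu1)^2
  k <- which.max(bc)
  (u[k] + u[k + 1L]) / 2
}

#' Remove background (and optionally dim) pixels by thresholding
#'
#' Produces the binary mask of pixels strictly above a threshold chosen by
#' one of three methods: `"otsu"` (default; automatic stand-in for the
#' manual visual threshold), `"fixed"` (explicit `value`) or `"percentile"`
#' (`p` percent of pixels fall at or below the threshold; quantile type 7).
#' With `exclude_dim = TRUE` a second Otsu split is applied within the
#' foreground, dropping the dimmer class -- this mirrors discarding nucleus
#' pixels while keeping the bright cytoplasm for image-level metrics.
#'
#' @param image numeric matrix.
#' @param method `"otsu"`, `"fixed"` or `"percentile"`.
#' @param value threshold for `method = "fixed"`.
#' @param p percentile in `[0, 100]` for `method = "percentile"`.
#' @param exclude_dim apply the second-stage Otsu split (default FALSE).
#' @return logical matrix with attributes `threshold`, `method` and
#'   `degenerate` (TRUE when Otsu saw a constant image; the mask is then
#'   empty and a warning is raised instead of an error).
#' @export
threshold_background <- function(image,
                                 method = c("otsu", "fixed", "percentile"),
                                 value = NULL, p = NULL,
                                 exclude_dim = FALSE) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  degenerate <- FALSE
  thr <- switch(method,
    fixed = {
      if (is.null(value)) stop("method 'fixed' needs `value`", call. = FALSE)
      value
    },
    percentile = {
      if (is.null(p) || p < 0 || p > 100)
        stop("method 'percentile' needs `p` in [0, 100]", call. = FALSE)
      stats::quantile(as.vector(image), p / 100, names = FALSE, type = 7)
    },
    otsu = otsu_threshold(image))
  if (is.na(thr)) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    degenerate <- TRUE
    thr <- Inf
  }
  mask <- image > thr
  if (exclude_dim && !degenerate && any(mask)) {
    thr2 <- otsu_threshold(image[mask])
    if (!is.na(thr2)) {
      mask <- mask & image > thr2
      thr <- c(background = thr, dim = thr2)
    }
  }
  structure(mask, threshold = thr, method = method, degenerate = degenerate)
}

# Connected-component labeling via column runs + union-find.
# connectivity 4 or 8; labels are assigned in scan order (deterministic).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (!any(mask)) return(lab)
  runs_by_col <- vector("list", W)
  run_col <- integer(0); run_start <- integer(0); run_end <- integer(0)
  nrun <- 0L
  for (j in seq_len(W)) {
    col <- mask[, j]
    if (!any(col)) { runs_by_col[[j]] <- integer(0); next }
    d <- diff(c(FALSE, col, FALSE))
    st <- which(d == 1L); en <- which(d == -1L) - 1L
    ids <- nrun + seq_along(st)
    nrun <- nrun + length(st)
    run_col <- c(run_col, rep.int(j, length(st)))
    run_start <- c(run_start, st); run_end <- c(run_end, en)
    runs_by_col[[j]] <- ids
  }
  parent <- seq_len(nrun)
  find_root <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  slack <- if (connectivity == 8L) 1L else 0L
  if (W >= 2L) {
    for (j in 2:W) {
      a <- runs_by_col[[j - 1L]]; b <- runs_by_col[[j]]
      if (!length(a) || !length(b)) next
      for (rb in b) {
        for (ra in a) {
          if (run_start[rb] <= run_end[ra] + slack &&
              run_end[rb] >= run_start[ra] - slack) {
            pa <- find_root(ra); pb <- find_root(rb)
            if (pa != pb) parent[pb] <- pa
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(nrun), find_root, integer(1))
  ids <- match(roots, unique(roots))
  for (r in seq_len(nrun)) {
    lab[run_start[r]:run_end[r], run_col[r]] <- ids[r]
  }
  lab
}

#' Fill holes in a binary mask
#'
#' Background components (4-connected) that do not touch the image border
#' are enclosed by foreground and are switched on. Used so that nucleus
#' pixels inside a cell belong to its ROI when tracing whole cells.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_mask_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  bg <- label_components(!mask, connectivity = 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole <- !(bg %in% c(0L, border))
  dim(hole) <- dim(mask)
  mask | hole
}

#' Segment cells from a thresholded image
#'
#' Labels the 8-connected components of the foreground mask, optionally
#' fills internal holes first (so a dim nucleus is part of its cell's ROI),
#' and discards components smaller than `min_area`. Touching cells are not
#' separated (no watershed) -- the intended inputs are fields of
#' non-touching cells. Labels are renumbered 1..N in image scan order.
#'
#' @param image image the mask was computed on (recorded for provenance;
#'   may be NULL).
#' @param mask logical matrix from [threshold_background()].
#' @param min_area minimum component area in pixels (default 100).
#' @param fill_holes fill enclosed background before labeling (default TRUE).
#' @param source_channel provenance string, e.g. `"451"`.
#' @return a `label_mask` object: list with `labels` (integer matrix,
#'   0 = background), `n_cells`, `provenance`.
#' @export
segment_cells <- function(image, mask, min_area = 100L, fill_holes = TRUE,
                          source_channel = "451") {
  stopifnot(is.matrix(mask))
  if (!is.null(image) && !all(dim(image) == dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  m <- mask
  if (fill_holes) m <- fill_mask_holes(m)
  lab <- label_components(m, connectivity = 8L)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_area)
    remap <- integer(length(areas))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  structure(list(labels = lab, n_cells = max(lab),
                 provenance = list(threshold = attr(mask, "threshold"),
                                   method = attr(mask, "method"),
                                   min_area = min_area,
                                   fill_holes = fill_holes,
                                   source_channel = source_channel)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d cell(s) on a %d x %d image (%s threshold on the %s channel)\n",
              x$n_cells, nrow(x$labels), ncol(x$labels),
              x$provenance$method %||% "?", x$provenance$source_channel))
  invisible(x)
}

#' Propagate static ROIs to every frame of both channels
#'
#' ROIs are static in time (one trace applied to all frames; no motion
#' tracking): the pixel membership of every cell is identical on each frame
#' and in both channels. Returns that membership in indexed form, the
#' representation [extract_traces()] consumes.
#'
#' @param label_mask a [segment_cells()] result (or bare integer matrix).
#' @param channel_stack a [channel_stack()]; used for shape validation.
#' @return list with `pixels` (list of pixel indices per cell), `n_pixels`,
#'   `cell_ids`, `n_frames`.
#' @export
propagate_rois <- function(label_mask, channel_stack) {
  labs <- if (inherits(label_mask, "label_mask")) label_mask$labels else label_mask
  d <- dim(channel_stack$data_451)
  if (!all(dim(labs) == d[1:2]))
    stop(sprintf("label mask (%d x %d) does not match frame shape (%d x %d)",
                 nrow(labs), ncol(labs), d[1], d[2]), call. = FALSE)
  ids <- sort(unique(labs[labs > 0L]))
  pixels <- lapply(ids, function(i) which(labs == i))
  list(pixels = pixels,
       n_pixels = lengths(pixels),
       cell_ids = ids,
       n_frames = d[3])
}
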