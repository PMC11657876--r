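#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average
#'
#' Smooths a numeric series with a centered box filter. Windows are truncated
#' at the series ends (the average runs over the available samples), so the
#' output has the same length as the input and no phase lag.
#'
#' @param x numeric vector.
#' @param window window width in samples; even values are rounded up to the
#'   next odd integer so the filter stays centered. `window <= 1` returns `x`.
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window) {
  n <- length(x)
  window <- as.integer(window)
  if (is.na(window) || window <= 1L || n == 0L) return(x)
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Integer translation of a matrix by (dy, dx), vacated pixels set to `fill`.
translate_img <- function(img, dy, dx, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  sr <- max(1L, 1L + dy):min(H, H + dy)   # destination rows
  sc <- max(1L, 1L + dx):min(W, W + dx)
  if (length(sr) > 0L && length(sc) > 0L && max(1L, 1L + dy) <= min(H, H + dy) &&
      max(1L, 1L + dx) <= min(W, W + dx)) {
    out[sr, sc] <- img[sr - dy, sc - dx]
  }
  out
}

# Cheap stable content hash for manifests (FNV-1a over serialized bytes).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

round1 <- function(x) round(x, 1)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
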