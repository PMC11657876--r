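# Minimal baseline TIFF codec: multi-page, single-sample grayscale, 8- or
# 16-bit, uncompressed. Reading accepts either byte order and any strip
# layout; writing emits little-endian uint16 (or uint8) with one strip per
# page. This covers exactly what a split-frame acquisition produces; RGB,
# tiled, or compressed files are rejected with explicit errors.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L)

rd_uint <- function(raw, off, size, endian) {
  b <- as.integer(raw[(off + 1L):(off + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1L))
}

rd_field_values <- function(raw, type, count, value_off, endian) {
  size <- TIFF_TYPE_SIZE[[as.character(type)]]
  total <- size * count
  # values of <= 4 bytes live inline in the entry, else value_off points at them
  data_off <- if (total <= 4L) value_off else rd_uint(raw, value_off, 4L, endian)
  if (type == 2L) {  # ASCII
    bytes <- raw[(data_off + 1L):(data_off + count)]
    return(rawToChar(bytes[bytes != as.raw(0L)]))
  }
  vapply(seq_len(count), function(i) {
    rd_uint(raw, data_off + (i - 1L) * size, size, endian)
  }, numeric(1))
}

decode_pixels <- function(raw, bits, endian) {
  if (bits == 8L) {
    as.integer(raw)
  } else {
    readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
            signed = FALSE, endian = endian)
  }
}

#' Read a multi-page grayscale TIFF
#'
#' Parses the IFD chain of a baseline TIFF and returns all pages as an
#' `H x W x T` integer array. Only single-sample (grayscale) uncompressed
#' pages are accepted; RGB or palette pages, compressed data, and pages with
#' inconsistent dimensions raise errors, as required for split-frame stacks.
#'
#' @param path path to a TIFF file.
#' @return list with `frames` (`H x W x T` integer array), `bits`
#'   (8 or 16) and `description` (ImageDescription tag of the first page,
#'   or `NULL`).
#' @seealso [write_tiff_stack()], [read_stack()]
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path, call. = FALSE)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path, call. = FALSE))
  if (rd_uint(raw, 2L, 2L, endian) != 42)
    stop("not a TIFF file (bad magic number): ", path, call. = FALSE)

  ifd_off <- rd_uint(raw, 4L, 4L, endian)
  pages <- list()
  description <- NULL
  bits_first <- NULL
  seen <- character(0)
  while (ifd_off != 0) {
    key <- as.character(ifd_off)
    if (key %in% seen) stop("corrupt TIFF: cyclic IFD chain", call. = FALSE)
    seen <- c(seen, key)
    n_entries <- rd_uint(raw, ifd_off, 2L, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      eoff <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd_uint(raw, eoff, 2L, endian)
      type <- rd_uint(raw, eoff + 2L, 2L, endian)
      count <- rd_uint(raw, eoff + 4L, 4L, endian)
      tags[[as.character(tag)]] <- rd_field_values(raw, type, count, eoff + 8L, endian)
    }
    width <- tags[["256"]]; height <- tags[["257"]]
    if (is.null(width) || is.null(height))
      stop("corrupt TIFF: page without dimensions", call. = FALSE)
    bits <- tags[["258"]] %||% 1
    spp <- tags[["277"]] %||% 1
    photometric <- tags[["262"]] %||% 1
    if (spp != 1 || length(bits) != 1 || photometric > 1)
      stop("unsupported TIFF: RGB/multi-sample pages are not grayscale stacks",
           call. = FALSE)
    if (!bits %in% c(8, 16))
      stop("unsupported TIFF: ", bits, "-bit samples (expected 8 or 16)", call. = FALSE)
    if ((tags[["259"]] %||% 1) != 1)
      stop("unsupported TIFF: compressed data", call. = FALSE)
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    if (is.null(offs) || is.null(cnts) || length(offs) != length(cnts))
      stop("corrupt TIFF: bad strip tables", call. = FALSE)
    strip_raw <- unlist(lapply(seq_along(offs), function(i) {
      raw[(offs[i] + 1L):(offs[i] + cnts[i])]
    }))
    vals <- decode_pixels(strip_raw, as.integer(bits), endian)
    if (length(vals) < width * height)
      stop("corrupt TIFF: truncated pixel data", call. = FALSE)
    pages[[length(pages) + 1L]] <-
      matrix(vals[seq_len(width * height)], nrow = height, ncol = width, byrow = TRUE)
    if (length(pages) == 1L) {
      description <- tags[["270"]]
      bits_first <- as.integer(bits)
    }
    ifd_off <- rd_uint(raw, ifd_off + 2L + n_entries * 12L, 4L, endian)
  }
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path, call. = FALSE)
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("TIFF pages have inconsistent sizes", call. = FALSE)
  frames <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]]
  list(frames = frames, bits = bits_first, description = description)
}

wr_u16 <- function(v) {
  v <- as.integer(v)
  r <- raw(2L * length(v))
  r[c(TRUE, FALSE)] <- as.raw(v %% 256L)
  r[c(FALSE, TRUE)] <- as.raw(v %/% 256L)
  r
}

wr_u32 <- function(v) {
  v <- as.numeric(v)
  r <- raw(4L * length(v))
  r[seq(1L, length(r), 4L)] <- as.raw(v %% 256)
  r[seq(2L, length(r), 4L)] <- as.raw((v %/% 256) %% 256)
  r[seq(3L, length(r), 4L)] <- as.raw((v %/% 65536) %% 256)
  r[seq(4L, length(r), 4L)] <- as.raw((v %/% 16777216) %% 256)
  r
}

tiff_entry <- function(tag, type, count, value) {
  c(wr_u16(c(tag, type)), wr_u32(count), value)
}

#' Write a multi-page grayscale TIFF
#'
#' Writes an `H x W x T` array (or a list of matrices) as an uncompressed
#' little-endian baseline TIFF, one page per frame, one strip per page.
#' Values are clipped to the representable range and rounded.
#'
#' @param frames `H x W x T` numeric array, `H x W` matrix, or list of
#'   equally sized matrices.
#' @param path output path.
#' @param bits 8 or 16 (default) bits per sample.
#' @param description optional character scalar stored in the
#'   ImageDescription tag of the first page (used for embedded JSON metadata).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, bits = 16L, description = NULL) {
  if (is.list(frames)) {
    frames <- simplify2array(frames)
  }
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 3L, bits %in% c(8L, 16L))
  H <- dim(frames)[1]; W <- dim(frames)[2]; T_ <- dim(frames)[3]
  vmax <- 2^bits - 1
  desc_raw <- NULL
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(as.character(description)), as.raw(0L))
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per_page <- H * W * (bits / 8L)
  n_entries <- function(page) 10L + (page == 1L && !is.null(desc_raw))
  # layout: header | page1 desc | page1 data | page1 IFD | page2 data | ...
  pos <- 8L
  desc_off <- NA
  if (!is.null(desc_raw)) { desc_off <- pos; pos <- pos + length(desc_raw) }
  data_off <- numeric(T_); ifd_off <- numeric(T_)
  for (t in seq_len(T_)) {
    data_off[t] <- pos; pos <- pos + bytes_per_page
    ifd_off[t] <- pos; pos <- pos + 2L + n_entries(t) * 12L + 4L
  }

  writeBin(charToRaw("II"), con)
  writeBin(wr_u16(42L), con)
  writeBin(wr_u32(ifd_off[1]), con)
  if (!is.null(desc_raw)) writeBin(desc_raw, con)
  for (t in seq_len(T_)) {
    v <- round(as.numeric(t(frames[, , t])))   # TIFF is row-major
    v[v < 0] <- 0; v[v > vmax] <- vmax
    writeBin(if (bits == 16L) wr_u16(v) else as.raw(as.integer(v)), con)
    entries <- list(
      tiff_entry(256L, 4L, 1L, wr_u32(W)),
      tiff_entry(257L, 4L, 1L, wr_u32(H)),
      tiff_entry(258L, 3L, 1L, c(wr_u16(bits), wr_u16(0L))),
      tiff_entry(259L, 3L, 1L, c(wr_u16(1L), wr_u16(0L))),
      tiff_entry(262L, 3L, 1L, c(wr_u16(1L), wr_u16(0L)))
    )
    if (t == 1L && !is.null(desc_raw)) {
      entries <- c(entries, list(tiff_entry(270L, 2L, length(desc_raw), wr_u32(desc_off))))
    }
    entries <- c(entries, list(
      tiff_entry(273L, 4L, 1L, wr_u32(data_off[t])),
      tiff_entry(277L, 3L, 1L, c(wr_u16(1L), wr_u16(0L))),
      tiff_entry(278L, 4L, 1L, wr_u32(H)),
      tiff_entry(279L, 4L, 1L, wr_u32(bytes_per_page)),
      tiff_entry(339L, 3L, 1L, c(wr_u16(1L), wr_u16(0L)))
    ))
    writeBin(wr_u16(length(entries)), con)
    for (e in entries) writeBin(e, con)
    writeBin(wr_u32(if (t < T_) ifd_off[t + 1L] else 0L), con)
  }
  invisible(path)
}
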