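#' @importFrom jsonlite fromJSON toJSON
NULL

# ---------------------------------------------------------------------------
# Minimal baseline TIFF I/O.
#
# No TIFF package exists in this R stack, so the subset of baseline TIFF the
# pipeline needs is implemented here: little-endian, uncompressed, single
# sample per pixel, 8/16-bit unsigned integer or 32/64-bit IEEE float,
# multi-page. Stack geometry and physical metadata are carried in a JSON
# ImageDescription tag so that write/read round-trips the full ImageStack.
# Pages are ordered channel-major: for c { for t { for z } }.
# ---------------------------------------------------------------------------

.tiff_type_ascii <- 2L; .tiff_type_short <- 3L; .tiff_type_long <- 4L

.write_entry <- function(con, tag, type, count, value_bytes) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  stopifnot(length(value_bytes) == 4L)
  writeBin(value_bytes, con)
}

.le2 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.le4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write an ImageStack to a multi-page TIFF
#'
#' @param img an [image_stack()].
#' @param path output file.
#' @param bits storage depth: 8 or 16 (unsigned integer) or 32 or 64
#'   (IEEE float). 16-bit storage of non-integer data loses precision.
#' @return `path`, invisibly.
#' @export
write_stack <- function(img, path, bits = 32L) {
  stopifnot(inherits(img, "ImageStack"))
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L, 32L, 64L)) stop("bits must be 8, 16, 32 or 64")
  is_float <- bits >= 32L
  d <- dim(img$data)
  w <- d[5]; h <- d[4]; n_pages <- d[1] * d[2] * d[3]
  if (!is_float) {
    mx <- if (bits == 8L) 255 else 65535
    if (any(img$data < 0) || any(img$data > mx) ||
        any(img$data != round(img$data)))
      stop("integer TIFF storage needs integral data in [0, ", mx, "]")
  }
  desc <- jsonlite::toJSON(list(
    axes = "ctzyx", dim = d,
    pixel_size_nm = img$pixel_size_nm, z_step_nm = img$z_step_nm,
    frame_interval_s = img$frame_interval_s,
    channel_names = img$channel_names), auto_unbox = TRUE, digits = NA)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))

  bytes_px <- bits %/% 8L
  strip_size <- w * h * bytes_px
  strip_off <- 8 + (seq_len(n_pages) - 1) * strip_size
  desc_off <- 8 + n_pages * strip_size
  ifd_start <- desc_off + length(desc_raw)
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  ifd_off <- ifd_start + (seq_len(n_pages) - 1) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  # pixel data, page by page (TIFF rows are top-down, row-major)
  page <- 0L
  for (ci in seq_len(d[1])) for (ti in seq_len(d[2])) for (zi in seq_len(d[3])) {
    page <- page + 1L
    v <- as.vector(t(img$data[ci, ti, zi, , ]))
    if (is_float) writeBin(as.numeric(v), con, size = bytes_px, endian = "little")
    else writeBin(as.integer(v), con, size = bytes_px, endian = "little")
  }
  writeBin(desc_raw, con)
  for (p in seq_len(n_pages)) {
    writeBin(n_entries, con, size = 2, endian = "little")
    .write_entry(con, 256, .tiff_type_long, 1, .le4(w))
    .write_entry(con, 257, .tiff_type_long, 1, .le4(h))
    .write_entry(con, 258, .tiff_type_short, 1, c(.le2(bits), as.raw(c(0, 0))))
    .write_entry(con, 259, .tiff_type_short, 1, c(.le2(1), as.raw(c(0, 0))))
    .write_entry(con, 262, .tiff_type_short, 1, c(.le2(1), as.raw(c(0, 0))))
    .write_entry(con, 270, .tiff_type_ascii, length(desc_raw), .le4(desc_off))
    .write_entry(con, 273, .tiff_type_long, 1, .le4(strip_off[p]))
    .write_entry(con, 278, .tiff_type_long, 1, .le4(h))
    .write_entry(con, 279, .tiff_type_long, 1, .le4(strip_size))
    .write_entry(con, 339, .tiff_type_short, 1,
                 c(.le2(if (is_float) 3 else 1), as.raw(c(0, 0))))
    next_ifd <- if (p < n_pages) ifd_off[p + 1] else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

.read_u2 <- function(raw, at, le) {
  b <- as.integer(raw[at + 0:1]); if (!le) b <- rev(b)
  b[1] + 256L * b[2]
}
.read_u4 <- function(raw, at, le) {
  b <- as.numeric(as.integer(raw[at + 0:3])); if (!le) b <- rev(b)
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

# read `count` values of a given TIFF field type from a raw buffer
.read_values <- function(raw, at, type, count, le) {
  if (type == .tiff_type_short) {
    vapply(seq_len(count), function(i) .read_u2(raw, at + 2 * (i - 1), le), 0)
  } else if (type == .tiff_type_long) {
    vapply(seq_len(count), function(i) .read_u4(raw, at + 4 * (i - 1), le), 0)
  } else if (type == .tiff_type_ascii) {
    rawToChar(raw[at + seq_len(count) - 1][raw[at + seq_len(count) - 1] != 0])
  } else if (type == 1L) { # BYTE
    as.integer(raw[at + seq_len(count) - 1])
  } else NULL
}

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

#' Read a TIFF (or raw-grid) file into an ImageStack
#'
#' Reads a single- or multi-page uncompressed TIFF (8/16-bit unsigned or
#' 32/64-bit float), or the package's plain-text grid format (see
#' [write_grid()]). Stacks written by [write_stack()] carry their axis
#' layout and physical metadata in the file and round-trip exactly;
#' third-party TIFFs are read with pages mapped to the time axis and
#' require a `pixel_size_nm` override.
#'
#' @param path input file.
#' @param pixel_size_nm,z_step_nm,frame_interval_s optional metadata
#'   overrides; an error is raised if the pixel size is neither stored nor
#'   overridden.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size_nm = NULL, z_step_nm = NULL,
                       frame_interval_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  head2 <- readBin(path, raw(), 2)
  if (!identical(rawToChar(head2), "II") && !identical(rawToChar(head2), "MM")) {
    return(.read_grid_impl(path, pixel_size_nm, z_step_nm, frame_interval_s))
  }
  buf <- readBin(path, raw(), file.size(path))
  le <- identical(rawToChar(buf[1:2]), "II")
  if (.read_u2(buf, 3, le) != 42) stop("not a TIFF file: ", path)
  ifd_off <- .read_u4(buf, 5, le)
  pages <- list(); desc <- NULL
  while (ifd_off > 0) {
    n <- .read_u2(buf, ifd_off + 1, le)
    tags <- list()
    for (i in seq_len(n)) {
      at <- ifd_off + 3 + 12 * (i - 1)
      tag <- .read_u2(buf, at, le)
      type <- .read_u2(buf, at + 2, le)
      count <- .read_u4(buf, at + 4, le)
      sz <- .tiff_type_size[[as.character(type)]]
      val_at <- if (is.null(sz) || sz * count > 4) .read_u4(buf, at + 8, le) + 1
                else at + 8
      tags[[as.character(tag)]] <- .read_values(buf, val_at, type, count, le)
    }
    need <- function(t) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) stop("TIFF missing required tag ", t)
      v
    }
    w <- need(256); h <- need(257)
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]][1]
    if (comp != 1) stop("only uncompressed TIFF is supported")
    fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]][1]
    offs <- need(273); counts <- need(279)
    if (!is.null(tags[["270"]]) && is.null(desc)) desc <- tags[["270"]]
    # concatenate strips, decode
    px_raw <- unlist(lapply(seq_along(offs), function(i)
      buf[offs[i] + seq_len(counts[i])]), use.names = FALSE)
    bytes_px <- bits %/% 8L
    npx <- length(px_raw) %/% bytes_px
    v <- if (fmt == 3) {
      readBin(px_raw, numeric(), npx, size = bytes_px,
              endian = if (le) "little" else "big")
    } else if (bits == 8L) {
      as.numeric(as.integer(px_raw))
    } else if (bits == 16L) {
      readBin(px_raw, integer(), npx, size = 2, signed = FALSE,
              endian = if (le) "little" else "big")
    } else stop("unsupported TIFF bit depth: ", bits)
    pages[[length(pages) + 1L]] <- matrix(as.numeric(v), nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd_off <- .read_u4(buf, ifd_off + 3 + 12 * n, le)
  }
  meta <- NULL
  if (!is.null(desc)) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    if (!is.null(meta) && !identical(meta$axes, "ctzyx")) meta <- NULL
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  if (!is.null(meta)) {
    d <- as.integer(meta$dim)
    if (prod(d[1:3]) != length(pages)) stop("TIFF page count does not match metadata")
    arr <- array(0, d)
    p <- 0L
    for (ci in seq_len(d[1])) for (ti in seq_len(d[2])) for (zi in seq_len(d[3])) {
      p <- p + 1L
      arr[ci, ti, zi, , ] <- pages[[p]]
    }
    img <- image_stack(arr,
      pixel_size_nm = if (!is.null(pixel_size_nm)) pixel_size_nm else meta$pixel_size_nm,
      z_step_nm = if (!is.null(z_step_nm)) z_step_nm else meta$z_step_nm,
      frame_interval_s = if (!is.null(frame_interval_s)) frame_interval_s else meta$frame_interval_s,
      channel_names = meta$channel_names)
    return(img)
  }
  if (is.null(pixel_size_nm))
    stop("pixel size not stored in file; supply `pixel_size_nm`")
  arr <- array(0, c(1L, length(pages), 1L, h, w))
  for (p in seq_along(pages)) arr[1, p, 1, , ] <- pages[[p]]
  image_stack(arr, pixel_size_nm = pixel_size_nm,
              z_step_nm = if (is.null(z_step_nm)) 0 else z_step_nm,
              frame_interval_s = if (is.null(frame_interval_s)) 0 else frame_interval_s)
}

# ---------------------------------------------------------------------------
# Plain-text raw grid format: a JSON header line followed by one whitespace-
# separated line of values per page. Used for small text fixtures.
# ---------------------------------------------------------------------------

#' Write an ImageStack as plain text
#'
#' The package's raw grid format: line 1 is a JSON header (axes, dims,
#' physical metadata); each following line holds one (c,t,z) page in
#' row-major order. Lossless for doubles.
#'
#' @param img an [image_stack()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid <- function(img, path) {
  stopifnot(inherits(img, "ImageStack"))
  d <- dim(img$data)
  hdr <- jsonlite::toJSON(list(
    format = "phagoquant-grid", axes = "ctzyx", dim = d,
    pixel_size_nm = img$pixel_size_nm, z_step_nm = img$z_step_nm,
    frame_interval_s = img$frame_interval_s,
    channel_names = img$channel_names), auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  for (ci in seq_len(d[1])) for (ti in seq_len(d[2])) for (zi in seq_len(d[3])) {
    v <- as.vector(t(img$data[ci, ti, zi, , ]))
    writeLines(paste(format(v, digits = 17, trim = TRUE, scientific = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

.read_grid_impl <- function(path, pixel_size_nm, z_step_nm, frame_interval_s) {
  lines <- readLines(path)
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e) NULL)
  if (is.null(hdr) || !identical(hdr$format, "phagoquant-grid"))
    stop("unreadable image file (neither TIFF nor phagoquant grid): ", path)
  d <- as.integer(hdr$dim)
  arr <- array(0, d)
  p <- 1L
  for (ci in seq_len(d[1])) for (ti in seq_len(d[2])) for (zi in seq_len(d[3])) {
    v <- as.numeric(strsplit(lines[1 + p], "[ \t]+")[[1]])
    arr[ci, ti, zi, , ] <- matrix(v, d[4], d[5], byrow = TRUE)
    p <- p + 1L
  }
  image_stack(arr,
    pixel_size_nm = if (!is.null(pixel_size_nm)) pixel_size_nm else hdr$pixel_size_nm,
    z_step_nm = if (!is.null(z_step_nm)) z_step_nm else hdr$z_step_nm,
    frame_interval_s = if (!is.null(frame_interval_s)) frame_interval_s else hdr$frame_interval_s,
    channel_names = hdr$channel_names)
}

#' Write a LabelMask as a 16-bit TIFF
#' @param mask a [label_mask()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "LabelMask"))
  img <- image_stack(matrix(as.numeric(mask$labels), nrow(mask$labels)),
                     pixel_size_nm = if (is.na(mask$pixel_size_nm)) 1 else mask$pixel_size_nm)
  write_stack(img, path, bits = 16L)
}

#' Read a LabelMask from a TIFF
#' @param path input file.
#' @param role region role, see [label_mask()].
#' @return a [label_mask()].
#' @export
read_mask <- function(path, role = "cell") {
  img <- read_stack(path, pixel_size_nm = 1)
  label_mask(matrix(as.integer(get_plane(img)), dim(img)[4]),
             role = role, pixel_size_nm = img$pixel_size_nm)
}
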