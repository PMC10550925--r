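#' Multi-dimensional fluorescence image stack
#'
#' An `ImageStack` is the package's container for fluorescence data: a 5-D
#' intensity array with fixed axis order (channel, time, z, y, x) plus the
#' physical metadata every assay formula needs (pixel pitch in nm, z step in
#' nm, frame interval in s). Single 2-D images are stacks with singleton
#' channel/time/z axes. y increases downward; pixel indices are 0-based in
#' physical terms (a pixel's site is its center); areas are reported as
#' pixel_count x pixel_size_nm^2.
#'
#' @param data numeric array. Accepted shapes: 2-D (y,x), 3-D (t,y,x) or
#'   5-D (c,t,z,y,x). Intensities must be finite.
#' @param pixel_size_nm physical pixel pitch, nm (> 0).
#' @param z_step_nm spacing between z planes, nm (>= 0).
#' @param frame_interval_s time between frames, s (>= 0).
#' @param channel_names optional character vector, one per channel.
#' @return an object of class `ImageStack`.
#' @examples
#' img <- image_stack(matrix(0, 8, 8), pixel_size_nm = 50)
#' dim(img$data)  # 1 1 1 8 8
#' @export
image_stack <- function(data, pixel_size_nm, z_step_nm = 0,
                        frame_interval_s = 0, channel_names = NULL) {
  if (is.matrix(data)) {
    data <- array(data, c(1L, 1L, 1L, nrow(data), ncol(data)))
  } else if (length(dim(data)) == 3L) {
    d <- dim(data)
    data <- array(aperm(data, c(1, 2, 3)), c(1L, d[1L], 1L, d[2L], d[3L]))
  } else if (length(dim(data)) != 5L) {
    stop("`data` must be a 2-D, 3-D (t,y,x) or 5-D (c,t,z,y,x) array")
  }
  if (!all(is.finite(data))) stop("intensities must be finite")
  storage.mode(data) <- "double"
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number")
  if (z_step_nm < 0 || frame_interval_s < 0)
    stop("`z_step_nm` and `frame_interval_s` must be >= 0")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(data)[1L]))
  if (length(channel_names) != dim(data)[1L])
    stop("`channel_names` length must equal the number of channels")
  structure(list(data = data,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 z_step_nm = as.numeric(z_step_nm),
                 frame_interval_s = as.numeric(frame_interval_s),
                 channel_names = as.character(channel_names)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "ImageStack: %d channel(s) x %d frame(s) x %d plane(s) x %d x %d px\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  pixel %.3g nm, z step %.3g nm, frame interval %.3g s\n",
              x$pixel_size_nm, x$z_step_nm, x$frame_interval_s))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Extract one 2-D plane from a stack
#'
#' @param img an `ImageStack`.
#' @param channel,frame,z 1-based indices.
#' @return numeric matrix (y, x).
#' @export
get_plane <- function(img, channel = 1L, frame = 1L, z = 1L) {
  stopifnot(inherits(img, "ImageStack"))
  img$data[channel, frame, z, , , drop = TRUE]
}

#' Replace one 2-D plane of a stack
#' @inheritParams get_plane
#' @param value numeric matrix with the stack's (y, x) extent.
#' @return the modified `ImageStack`.
#' @export
set_plane <- function(img, value, channel = 1L, frame = 1L, z = 1L) {
  stopifnot(inherits(img, "ImageStack"))
  img$data[channel, frame, z, , ] <- value
  img
}

#' Background subtraction
#'
#' Subtracts a per-plane scalar background from every (channel, frame, z)
#' plane and clamps negatives to zero, mirroring the "background-subtracted
#' images" every downstream assay assumes. Two estimators are available: a
#' low percentile of each plane (default 1st percentile, a stand-in when no
#' cell-free region is available) or the mean over a user-supplied
#' background region.
#'
#' @param img an `ImageStack`.
#' @param method `"percentile"` or `"region"`.
#' @param param for `"percentile"`, a percentile in (0, 100); for
#'   `"region"`, a `LabelMask` whose nonzero pixels are background.
#' @return an `ImageStack` with non-negative intensities.
#' @examples
#' img <- image_stack(matrix(10, 4, 4), pixel_size_nm = 50)
#' range(background_subtract(img, "percentile", 1)$data)  # 0 0
#' @export
background_subtract <- function(img, method = c("percentile", "region"),
                                param = 1) {
  stopifnot(inherits(img, "ImageStack"))
  method <- match.arg(method)
  d <- dim(img$data)
  if (method == "percentile") {
    if (!is.numeric(param) || param <= 0 || param >= 100)
      stop("percentile `param` must lie in (0, 100)")
  } else {
    if (!inherits(param, "LabelMask")) stop("`param` must be a LabelMask")
    sel <- param$labels > 0L
    if (!any(sel)) stop("background region mask is empty")
  }
  for (ci in seq_len(d[1])) for (ti in seq_len(d[2])) for (zi in seq_len(d[3])) {
    pl <- img$data[ci, ti, zi, , ]
    bg <- if (method == "percentile") {
      stats::quantile(pl, param / 100, names = FALSE)
    } else {
      mean(pl[sel])
    }
    img$data[ci, ti, zi, , ] <- pmax(pl - bg, 0)
  }
  img
}

#' Project a stack along z
#'
#' Collapses the z axis by maximum or sum, the two reducers used for
#' quantification (max projections for lipid-probe stacks and the fusion
#' assay, sum projections for bead antigen fluorescence). Physical metadata
#' is preserved; the result has a singleton z axis.
#'
#' @param img an `ImageStack`.
#' @param mode `"max"` or `"sum"`.
#' @param axis only `"z"` is supported.
#' @return an `ImageStack` with one z plane.
#' @export
project <- function(img, mode = c("max", "sum"), axis = "z") {
  stopifnot(inherits(img, "ImageStack"))
  mode <- match.arg(mode)
  if (!identical(axis, "z")) stop("only z projection is supported")
  d <- dim(img$data)
  out <- array(0, c(d[1], d[2], 1L, d[4], d[5]))
  red <- if (mode == "max") function(a) apply(a, c(2, 3), max) else
    function(a) apply(a, c(2, 3), sum)
  for (ci in seq_len(d[1])) for (ti in seq_len(d[2])) {
    planes <- array(img$data[ci, ti, , , ], c(d[3], d[4], d[5]))
    out[ci, ti, 1L, , ] <- red(planes)
  }
  img$data <- out
  img
}
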