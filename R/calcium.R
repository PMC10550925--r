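#' Ratiometric Ca2+ trace for one cell
#'
#' Per-cell F340/F380 excitation-ratio time series from Fura-2 imaging,
#' anchored to the time of extracellular Ca2+ re-addition.
#'
#' @param t_s sample times, s (strictly increasing; 3 s frame interval in
#'   the reference protocol).
#' @param ratio F340/F380 values (> 0; non-finite frames are flagged
#'   invalid, not dropped).
#' @param readd_time_s Ca2+ re-addition time, s.
#' @param cell_id optional identifier.
#' @return an object of class `RatioTrace`.
#' @export
ratio_trace <- function(t_s, ratio, readd_time_s, cell_id = NA_integer_) {
  stopifnot(length(t_s) == length(ratio))
  if (any(diff(t_s) <= 0)) stop("times must be strictly increasing")
  valid <- is.finite(ratio) & ratio > 0
  structure(list(t_s = as.numeric(t_s), ratio = as.numeric(ratio),
                 valid = valid, readd_time_s = as.numeric(readd_time_s),
                 cell_id = as.integer(cell_id)),
            class = "RatioTrace")
}

#' @export
print.RatioTrace <- function(x, ...) {
  cat(sprintf("RatioTrace: %d samples, re-addition at %.0f s\n",
              length(x$t_s), x$readd_time_s))
  invisible(x)
}

#' Per-cell Fura-2 ratio traces from 340/380 nm channel stacks
#'
#' For every cell label, mean F340 over the cell divided by mean F380,
#' frame by frame. Frames with a zero denominator are flagged invalid.
#' Inputs are assumed registered and background-subtracted.
#'
#' @param f340,f380 single-channel [image_stack()]s with equal geometry.
#' @param cell_mask a [label_mask()] of cells.
#' @param readd_time_s Ca2+ re-addition time passed to each trace.
#' @return list of [ratio_trace()]s, one per cell label.
#' @export
fura_ratio <- function(f340, f380, cell_mask, readd_time_s = NA_real_) {
  stopifnot(inherits(f340, "ImageStack"), inherits(f380, "ImageStack"),
            inherits(cell_mask, "LabelMask"))
  if (!all(dim(f340) == dim(f380))) stop("channel stacks differ in geometry")
  n_t <- dim(f340)[2]
  dt <- if (f340$frame_interval_s > 0) f340$frame_interval_s else 3
  lapply(cell_mask$label_ids, function(cl) {
    sel <- cell_mask$labels == cl
    num <- vapply(seq_len(n_t), function(ti) mean(get_plane(f340, frame = ti)[sel]), 0)
    den <- vapply(seq_len(n_t), function(ti) mean(get_plane(f380, frame = ti)[sel]), 0)
    r <- ifelse(den > 0, num / den, NA_real_)
    ratio_trace(t_s = (seq_len(n_t) - 1) * dt, ratio = r,
                readd_time_s = readd_time_s, cell_id = cl)
  })
}

#' Store-operated Ca2+ entry metrics
#'
#' Classical SOCE readout: after ER store depletion in Ca2+-free medium,
#' extracellular Ca2+ is re-added and the response is summarised by the
#' peak amplitude (maximum post-re-addition ratio minus the pre-re-addition
#' baseline) and the maximum slope (largest slope of least-squares line
#' fits over sliding windows of `slope_window_pts` consecutive
#' post-re-addition samples).
#'
#' @param trace a [ratio_trace()] whose re-addition time lies inside the
#'   trace.
#' @param baseline_window_s length of the baseline window ending at
#'   re-addition, s.
#' @param slope_window_pts sliding-window length in samples (default 5).
#' @return list with `max_slope` (ratio/s), `peak_amplitude` (ratio units),
#'   `baseline`.
#' @export
soce_metrics <- function(trace, baseline_window_s, slope_window_pts = 5L) {
  stopifnot(inherits(trace, "RatioTrace"))
  t0 <- trace$readd_time_s
  if (!is.finite(t0) || t0 <= min(trace$t_s) || t0 > max(trace$t_s))
    stop("re-addition time must lie inside the trace")
  pre <- trace$t_s >= t0 - baseline_window_s & trace$t_s < t0 & trace$valid
  if (!any(pre)) stop("no baseline samples in the window")
  post <- trace$t_s >= t0 & trace$valid
  if (sum(post) < slope_window_pts)
    stop("too few post-re-addition samples for the slope window")
  baseline <- mean(trace$ratio[pre])
  y <- trace$ratio[post]; t <- trace$t_s[post]
  peak_amplitude <- max(y) - baseline
  n <- length(y)
  slopes <- vapply(seq_len(n - slope_window_pts + 1L), function(i) {
    ii <- i:(i + slope_window_pts - 1L)
    tt <- t[ii] - mean(t[ii])
    sum(tt * (y[ii] - mean(y[ii]))) / sum(tt^2)
  }, 0)
  list(max_slope = max(slopes), peak_amplitude = peak_amplitude,
       baseline = baseline)
}

#' Detect periphagosomal Ca2+ hotspots
#'
#' Implements the Fluo-8 hotspot rule: after temporal averaging, connected
#' regions of at least `min_area_px` pixels whose fluorescence exceeds the
#' cytosolic mean by `k_sd` cytosolic standard deviations, lying within
#' `max_dist_nm` of a phagosome border, are hotspots; each is assigned to
#' its nearest phagosome. Also returns the F/F_ave map (every pixel divided
#' by the cytosolic mean).
#'
#' @param fluo8 an [image_stack()]; multiple frames are averaged first
#'   (the 6 s temporal averaging step).
#' @param cyto_mask cytosol [label_mask()] (nonzero = cytosol); must be
#'   non-empty.
#' @param phag_mask phagosome [label_mask()].
#' @param k_sd threshold in cytosolic SD units (default 2).
#' @param max_dist_nm maximum centroid distance from the phagosomal border
#'   (default 750 nm, 3 pixels at 250 nm pitch).
#' @param min_area_px minimum hotspot area (default 4 px).
#' @param connectivity component connectivity (default 8).
#' @return object of class `HotspotSet`: data.frame `hotspots` (centroid,
#'   area, peak F/F_ave, phagosome), `per_phagosome` counts,
#'   `frequency` (hotspots per phagosome), `f_over_fave` map, `threshold`.
#' @export
detect_hotspots <- function(fluo8, cyto_mask, phag_mask, k_sd = 2,
                            max_dist_nm = 750, min_area_px = 4L,
                            connectivity = 8L) {
  stopifnot(inherits(fluo8, "ImageStack"), inherits(cyto_mask, "LabelMask"),
            inherits(phag_mask, "LabelMask"))
  d <- dim(fluo8)
  plane <- get_plane(fluo8)
  if (d[2] > 1) {
    for (ti in 2:d[2]) plane <- plane + get_plane(fluo8, frame = ti)
    plane <- plane / d[2]
  }
  cy <- cyto_mask$labels > 0L
  if (!any(cy)) stop("cytosol mask is empty")
  mu <- mean(plane[cy]); sdev <- stats::sd(plane[cy])
  if (!is.finite(sdev)) sdev <- 0
  thr <- mu + k_sd * sdev
  max_dist_px <- max_dist_nm / fluo8$pixel_size_nm
  # search outside the phagosome interior; distance gating comes next
  comp <- .components_above(plane, phag_mask$labels == 0L, thr, min_area_px,
                            connectivity)
  nr <- nearest_region(phag_mask$labels, ceiling(max_dist_px) + 2)
  keep <- logical(nrow(comp)); lab <- integer(nrow(comp)); dist <- numeric(nrow(comp))
  h <- nrow(plane); w <- ncol(plane)
  for (i in seq_len(nrow(comp))) {
    yy <- min(max(round(comp$centroid_y[i]), 1L), h)
    xx <- min(max(round(comp$centroid_x[i]), 1L), w)
    dist[i] <- nr$dist[yy, xx]
    lab[i] <- nr$label[yy, xx]
    keep[i] <- is.finite(dist[i]) && dist[i] <= max_dist_px
  }
  hs <- comp[keep, , drop = FALSE]
  hs$phagosome_id <- lab[keep]
  hs$border_dist_nm <- dist[keep] * fluo8$pixel_size_nm
  hs$area_nm2 <- hs$area_px * fluo8$pixel_size_nm^2
  hs$peak_F_over_Fave <- hs$mean_intensity / mu
  ids <- phag_mask$label_ids
  per <- stats::setNames(integer(length(ids)), ids)
  if (nrow(hs)) {
    tb <- table(factor(hs$phagosome_id, levels = ids))
    per[] <- as.integer(tb)
  }
  structure(list(hotspots = hs, per_phagosome = per,
                 frequency = if (length(ids)) sum(per) / length(ids) else NA_real_,
                 f_over_fave = plane / mu, threshold = thr),
            class = "HotspotSet")
}

#' @export
print.HotspotSet <- function(x, ...) {
  cat(sprintf("HotspotSet: %d hotspot(s), %.3f per phagosome\n",
              nrow(x$hotspots), x$frequency))
  invisible(x)
}

#' Phagocytic index
#'
#' Internalised targets per 100 cells.
#'
#' @param phag_mask phagosome [label_mask()].
#' @param cell_mask cell [label_mask()] (must contain at least one cell).
#' @return a single number.
#' @export
phagocytic_index <- function(phag_mask, cell_mask) {
  stopifnot(inherits(phag_mask, "LabelMask"), inherits(cell_mask, "LabelMask"))
  n_cells <- length(cell_mask$label_ids)
  if (n_cells == 0) stop("no cells in mask")
  100 * length(phag_mask$label_ids) / n_cells
}
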