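#' Detect ER-plasma-membrane contact puncta in a TIRF frame
#'
#' Puncta are connected regions strictly above a per-cell threshold of
#' whole-cell mean fluorescence plus one within-cell standard deviation,
#' with area strictly greater than `min_area_px` pixels. The frame is
#' assumed background-subtracted.
#'
#' @param frame an [image_stack()] (first channel/frame/plane analysed).
#' @param cell_mask cell [label_mask()] (non-empty).
#' @param min_area_px puncta must exceed this area (default 4, strict >).
#' @param frame_index which frame of a multi-frame stack to analyse.
#' @param connectivity component connectivity (default 8).
#' @return a `PunctaSet` with per-cell `counts` and per-cell mean areas in
#'   `mean_area_px`.
#' @export
detect_tirf_puncta <- function(frame, cell_mask, min_area_px = 4L,
                               frame_index = 1L, connectivity = 8L) {
  stopifnot(inherits(frame, "ImageStack"), inherits(cell_mask, "LabelMask"))
  if (!length(cell_mask$label_ids)) stop("cell mask is empty")
  plane <- get_plane(frame, frame = frame_index)
  rows <- list()
  ids <- cell_mask$label_ids
  counts <- stats::setNames(integer(length(ids)), ids)
  mean_area <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (cl in ids) {
    sel <- cell_mask$labels == cl
    thr <- mean(plane[sel]) + stats::sd(plane[sel])
    comp <- .components_above(plane, sel, thr, min_area_px + 1L, connectivity)
    counts[as.character(cl)] <- nrow(comp)
    if (nrow(comp)) {
      mean_area[as.character(cl)] <- mean(comp$area_px)
      comp$cell_id <- cl
      rows[[length(rows) + 1L]] <- comp
    }
  }
  puncta <- if (length(rows)) do.call(rbind, rows) else
    data.frame(centroid_y = numeric(0), centroid_x = numeric(0),
               area_px = integer(0), mean_intensity = numeric(0),
               cell_id = integer(0))
  puncta$area_nm2 <- puncta$area_px * frame$pixel_size_nm^2
  structure(list(puncta = puncta, counts = counts, mean_area_px = mean_area,
                 source_region = "whole_cell"),
            class = "PunctaSet")
}

#' Per-cell puncta number and size tracks from a TIRF movie
#'
#' Applies [detect_tirf_puncta()] to every frame and returns, per cell, the
#' puncta count and mean puncta area against a shared clock, plus the
#' baseline-frame detection used by [exclude_baseline_cells()].
#'
#' @param stack an [image_stack()] movie (1 frame/s in the reference
#'   protocol).
#' @param cell_mask cell [label_mask()].
#' @param min_area_px per-frame detection area rule (default 4, strict >).
#' @return object of class `TirfSeries`: `t_s`, per-cell matrices `n` and
#'   `mean_area_px` (frames x cells), `baseline` (a `PunctaSet`),
#'   `pixel_size_nm`.
#' @export
puncta_timeseries <- function(stack, cell_mask, min_area_px = 4L) {
  stopifnot(inherits(stack, "ImageStack"))
  n_t <- dim(stack)[2]
  dt <- if (stack$frame_interval_s > 0) stack$frame_interval_s else 1
  ids <- cell_mask$label_ids
  n_mat <- matrix(0L, n_t, length(ids), dimnames = list(NULL, ids))
  a_mat <- matrix(NA_real_, n_t, length(ids), dimnames = list(NULL, ids))
  baseline <- NULL
  for (ti in seq_len(n_t)) {
    ps <- detect_tirf_puncta(stack, cell_mask, min_area_px, frame_index = ti)
    if (ti == 1L) baseline <- ps
    n_mat[ti, ] <- ps$counts
    a_mat[ti, ] <- ps$mean_area_px
  }
  structure(list(t_s = (seq_len(n_t) - 1) * dt, n = n_mat,
                 mean_area_px = a_mat, baseline = baseline,
                 cell_ids = ids, pixel_size_nm = stack$pixel_size_nm),
            class = "TirfSeries")
}

#' Exclude cells with pre-existing contact puncta
#'
#' Cells already showing puncta larger than `max_baseline_area_nm2` in the
#' baseline (first) frame are removed from the analysis, since their
#' contact sites predate the stimulus. The default bound is the detection
#' area rule itself (4 pixels), i.e. any detectable baseline punctum
#' excludes the cell.
#'
#' @param series a `TirfSeries` from [puncta_timeseries()].
#' @param max_baseline_area_nm2 area bound; default `NULL` = 4 pixels at
#'   the series' pixel pitch.
#' @return the filtered `TirfSeries`, with an `excluded` data.frame log.
#' @export
exclude_baseline_cells <- function(series, max_baseline_area_nm2 = NULL) {
  stopifnot(inherits(series, "TirfSeries"))
  if (is.null(max_baseline_area_nm2))
    max_baseline_area_nm2 <- 4 * series$pixel_size_nm^2
  bp <- series$baseline$puncta
  bad <- unique(bp$cell_id[bp$area_nm2 > max_baseline_area_nm2])
  keep <- !(series$cell_ids %in% bad)
  log <- data.frame(cell_id = series$cell_ids, excluded = !keep)
  series$n <- series$n[, keep, drop = FALSE]
  series$mean_area_px <- series$mean_area_px[, keep, drop = FALSE]
  series$cell_ids <- series$cell_ids[keep]
  series$excluded <- log
  series
}

#' Fit a Boltzmann sigmoid to recruitment kinetics
#'
#' Least-squares fit of y(t) = A1 + (A2 - A1) / (1 + exp((t50 - t)/slope)),
#' the model used for contact-site recruitment time courses: A1/A2 are the
#' baseline and final plateaus, t50 the half-rise time and `slope` the
#' (time-unit) steepness parameter. Initialisation: A1 = min(y),
#' A2 = max(y), t50 = first half-range crossing, slope = (t90 - t10)/4.4;
#' the optimisation is bounded with slope > 0.
#'
#' @param t,y numeric vectors (>= 6 points spanning the rise).
#' @param stimulus_time_s time origin; reported `t50_s` is relative to it.
#' @return an object of class `boltzmann_fit` with components `A1`, `A2`,
#'   `t50_s`, `slope_s`, `rss`, `converged`, `degenerate`; methods `print`,
#'   `coef`, `predict`, `residuals` are available.
#' @examples
#' t <- 0:400
#' y <- 2 + 8 / (1 + exp((180 - t) / 30))
#' coef(fit_boltzmann(t, y))
#' @export
fit_boltzmann <- function(t, y, stimulus_time_s = 0) {
  stopifnot(length(t) == length(y))
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(y) < 6) stop("need at least 6 points to fit")
  out <- list(A1 = NA_real_, A2 = NA_real_, t50_s = NA_real_,
              slope_s = NA_real_, rss = NA_real_, converged = FALSE,
              degenerate = FALSE, t = t, y = y,
              stimulus_time_s = stimulus_time_s)
  if (max(y) - min(y) < .Machine$double.eps^0.5 * max(1, abs(max(y)))) {
    out$A1 <- out$A2 <- mean(y)
    out$rss <- sum((y - mean(y))^2)
    out$degenerate <- TRUE
    class(out) <- "boltzmann_fit"
    return(out)
  }
  a1 <- min(y); a2 <- max(y)
  cross <- function(q) {
    lev <- a1 + q * (a2 - a1)
    i <- which(y >= lev)[1]
    if (is.na(i)) t[length(t)] else t[i]
  }
  t10 <- cross(0.1); t50 <- cross(0.5); t90 <- cross(0.9)
  s0 <- max((t90 - t10) / 4.4, diff(range(t)) / (10 * length(t)), 1e-3)
  fit <- tryCatch(
    stats::nls(y ~ A1 + (A2 - A1) / (1 + exp((t50 - t) / slope)),
               start = list(A1 = a1, A2 = a2, t50 = t50, slope = s0),
               algorithm = "port",
               lower = c(A1 = -Inf, A2 = -Inf, t50 = -Inf, slope = 1e-6),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    class(out) <- "boltzmann_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  out$A1 <- unname(cf["A1"]); out$A2 <- unname(cf["A2"])
  out$t50_s <- unname(cf["t50"]) - stimulus_time_s
  out$slope_s <- unname(cf["slope"])
  out$rss <- sum(stats::resid(fit)^2)
  out$converged <- fit$convInfo$isConv
  class(out) <- "boltzmann_fit"
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Boltzmann fit: degenerate (constant y = %.4g)\n", x$A1))
  } else {
    cat(sprintf(
      "Boltzmann fit: A1 = %.4g, A2 = %.4g, t50 = %.4g s, slope = %.4g s (%s)\n",
      x$A1, x$A2, x$t50_s, x$slope_s,
      if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(A1 = object$A1, A2 = object$A2, t50_s = object$t50_s,
    slope_s = object$slope_s)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$t else
    if (is.list(newdata)) newdata$t else newdata
  if (object$degenerate) return(rep(object$A1, length(t)))
  t50_abs <- object$t50_s + object$stimulus_time_s
  object$A1 + (object$A2 - object$A1) /
    (1 + exp((t50_abs - t) / object$slope_s))
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  object$y - predict(object)
}

#' Track value nearest a given time
#'
#' Convenience accessor for "value at 6 min after stimulus"-style
#' quantities: returns the track value at the sample nearest `at_s`.
#'
#' @param t_s,values the track.
#' @param at_s query time, s.
#' @return the value at the nearest sample.
#' @export
value_at_time <- function(t_s, values, at_s) {
  values[which.min(abs(t_s - at_s))]
}
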