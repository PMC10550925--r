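#' Per-cell phagolysosome fusion index from a three-channel FRET assay
#'
#' Lysosomes are pre-loaded with an acceptor dye, targets carry the donor;
#' fusion brings the dyes together and produces FRET in the phagosome. The
#' PLF index is, per cell: the phagosomal FRET/donor(green) pixel ratio
#' averaged within each phagosome, summed over the cell's phagosomes, and
#' divided by the cell's total acceptor (red) fluorescence. A
#' green-independent FRET ratio (phagosomal FRET sum over total red) is
#' reported alongside. Stacks are max-projected first.
#'
#' @param fret,green,red registered, background-subtracted
#'   [image_stack()]s.
#' @param phag_mask phagosome [label_mask()].
#' @param cell_mask cell [label_mask()].
#' @return data.frame of class `PlfMeasurement`: one row per cell with
#'   `plf_index`, `fret_ratio`, `acceptor_loading`, `phagosome_count`,
#'   `frac_green_excluded`, `flagged`. Cells with no phagosome get
#'   `plf_index = NA` (undefined, not zero).
#' @export
plf_index <- function(fret, green, red, phag_mask, cell_mask) {
  for (s in list(fret, green, red)) stopifnot(inherits(s, "ImageStack"))
  if (!all(dim(fret) == dim(green)) || !all(dim(fret) == dim(red)))
    stop("channel stacks differ in geometry")
  pf <- get_plane(if (dim(fret)[3] > 1) project(fret, "max") else fret)
  pg <- get_plane(if (dim(green)[3] > 1) project(green, "max") else green)
  pr <- get_plane(if (dim(red)[3] > 1) project(red, "max") else red)
  cells <- cell_mask$label_ids
  # phagosome -> cell assignment by majority overlap
  cell_of <- vapply(phag_mask$label_ids, function(pl) {
    cl <- cell_mask$labels[phag_mask$labels == pl]
    cl <- cl[cl > 0L]
    if (!length(cl)) NA_integer_ else as.integer(names(which.max(table(cl))))
  }, 0L)
  out <- do.call(rbind, lapply(cells, function(cl) {
    csel <- cell_mask$labels == cl
    acceptor <- sum(pr[csel])
    phs <- phag_mask$label_ids[which(cell_of == cl)]
    if (!length(phs)) {
      return(data.frame(cell_id = cl, plf_index = NA_real_,
                        fret_ratio = NA_real_, acceptor_loading = acceptor,
                        phagosome_count = 0L, frac_green_excluded = NA_real_,
                        flagged = TRUE))
    }
    m_sum <- 0; fret_sum <- 0; n_excl <- 0L; n_px <- 0L; any_flag <- FALSE
    for (pl in phs) {
      sel <- phag_mask$labels == pl
      g <- pg[sel]; f <- pf[sel]
      ok <- g > 0
      n_excl <- n_excl + sum(!ok); n_px <- n_px + length(g)
      if (mean(!ok) > 0.5) any_flag <- TRUE
      if (any(ok)) m_sum <- m_sum + mean(f[ok] / g[ok])
      fret_sum <- fret_sum + sum(f)
    }
    if (acceptor <= 0) stop("zero acceptor loading in cell ", cl)
    data.frame(cell_id = cl, plf_index = m_sum / acceptor,
               fret_ratio = fret_sum / acceptor, acceptor_loading = acceptor,
               phagosome_count = length(phs),
               frac_green_excluded = n_excl / n_px, flagged = any_flag)
  }))
  class(out) <- c("PlfMeasurement", "data.frame")
  out
}

#' Fit a ratiometric pH calibration curve
#'
#' In-situ calibration: cells equilibrated in ionophore-containing buffers
#' of known pH (4-9), imaged at the two excitation wavelengths. Per-buffer
#' mean 440/480 ratios are fitted with a monotone Boltzmann of ratio
#' against pH; the sigmoid direction (the FITC ratio falls as pH rises) is
#' auto-detected. The fit is rejected when the buffer means are not
#' substantially monotone: any reversal larger than 5% of the dynamic
#' range, or a flat series, triggers an error with diagnostics.
#'
#' @param images list, one element per buffer, each
#'   `list(ex440 = ImageStack, ex480 = ImageStack)`.
#' @param buffer_ph numeric vector of buffer pH values; >= 4 distinct
#'   points spanning >= 3 pH units.
#' @return an object of class `ph_calibration`: `buffer_ph`, `mean_ratio`,
#'   `fit` (top, bottom, ph50, slope, direction), `valid_range`; methods
#'   `print`, `coef`, `predict` (ratio at pH).
#' @export
fit_ph_calibration <- function(images, buffer_ph) {
  stopifnot(length(images) == length(buffer_ph))
  if (length(unique(buffer_ph)) < 4 || diff(range(buffer_ph)) < 3)
    stop("need >= 4 distinct buffer pH values spanning >= 3 pH units")
  ratio <- vapply(images, function(b) {
    mean(b$ex440$data) / mean(b$ex480$data)
  }, 0)
  ord <- order(buffer_ph)
  ph <- buffer_ph[ord]; r <- ratio[ord]
  rng <- diff(range(r))
  if (rng < .Machine$double.eps^0.5 * max(abs(r)))
    stop("calibration rejected: constant ratios")
  dr <- diff(r)
  descending <- sum(dr) < 0
  reversal <- if (descending) max(c(dr, 0)) else max(c(-dr, 0))
  if (reversal > 0.05 * rng)
    stop(sprintf(
      "calibration rejected: non-monotone buffer means (reversal %.3g of range %.3g)",
      reversal, rng))
  sgn <- if (descending) 1 else -1
  fit <- tryCatch(
    stats::nls(r ~ bottom + (top - bottom) / (1 + exp(sgn * (ph - ph50) / s)),
               start = list(top = max(r), bottom = min(r),
                            ph50 = stats::median(ph), s = 0.5),
               algorithm = "port",
               lower = c(top = -Inf, bottom = -Inf, ph50 = min(ph) - 2, s = 1e-3),
               upper = c(top = Inf, bottom = Inf, ph50 = max(ph) + 2, s = 10),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) stop("calibration fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  cal <- structure(list(buffer_ph = ph, mean_ratio = r,
                        fit = list(top = unname(cf["top"]),
                                   bottom = unname(cf["bottom"]),
                                   ph50 = unname(cf["ph50"]),
                                   slope = unname(cf["s"]),
                                   direction = if (descending) "descending" else "ascending"),
                        valid_range = range(ph)),
                   class = "ph_calibration")
  # round-trip sanity at the buffer points (interior points, away from the
  # plateaus where the inverse is ill-conditioned)
  interior <- ph > min(ph) + 0.5 & ph < max(ph) - 0.5
  rt <- vapply(which(interior), function(i)
    abs(ratio_to_ph(predict(cal, ph[i]), cal, quiet = TRUE) - ph[i]), 0)
  cal$roundtrip_max_err <- if (length(rt)) max(rt) else NA_real_
  cal
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(sprintf(
    "pH calibration: %d buffers (pH %.1f-%.1f), %s Boltzmann, pH50 = %.2f, slope = %.2f\n",
    length(x$buffer_ph), x$valid_range[1], x$valid_range[2],
    x$fit$direction, x$fit$ph50, x$fit$slope))
  invisible(x)
}

#' @export
coef.ph_calibration <- function(object, ...) {
  with(object$fit, c(top = top, bottom = bottom, ph50 = ph50, slope = slope))
}

#' @export
predict.ph_calibration <- function(object, newdata = NULL, ...) {
  ph <- if (is.null(newdata)) object$buffer_ph else
    if (is.list(newdata)) newdata$ph else newdata
  sgn <- if (object$fit$direction == "descending") 1 else -1
  with(object$fit, bottom + (top - bottom) / (1 + exp(sgn * (ph - ph50) / slope)))
}

#' Convert a measured ratio to pH via the calibration curve
#'
#' Analytic inverse of the fitted Boltzmann. Ratios outside the fitted
#' ratio range are clamped to the valid pH range with a warning
#' (extrapolating a sigmoid plateau is meaningless).
#'
#' @param ratio measured 440/480 ratio(s).
#' @param cal a [fit_ph_calibration()] result.
#' @param quiet suppress the clamping warning.
#' @return pH value(s).
#' @export
ratio_to_ph <- function(ratio, cal, quiet = FALSE) {
  stopifnot(inherits(cal, "ph_calibration"))
  f <- cal$fit
  sgn <- if (f$direction == "descending") 1 else -1
  lo_r <- predict(cal, cal$valid_range[2]); hi_r <- predict(cal, cal$valid_range[1])
  rmin <- min(lo_r, hi_r); rmax <- max(lo_r, hi_r)
  out_of_range <- ratio <= rmin | ratio >= rmax
  if (any(out_of_range) && !quiet)
    warning("ratio outside calibrated range; pH clamped to valid range")
  ratio <- pmin(pmax(ratio, rmin + 1e-12), rmax - 1e-12)
  arg <- (f$top - ratio) / (ratio - f$bottom)
  arg <- pmax(arg, 1e-12)
  ph <- f$ph50 + sgn * f$slope * log(arg)
  pmin(pmax(ph, cal$valid_range[1]), cal$valid_range[2])
}

#' Mean phagosomal pH of a two-excitation image pair
#'
#' Per-phagosome mean 440/480 ratio converted through the calibration.
#'
#' @param ex440,ex480 [image_stack()]s (registered, background-subtracted).
#' @param phag_mask phagosome [label_mask()].
#' @param cal a [fit_ph_calibration()] result.
#' @return data.frame: `phagosome_id`, `ratio`, `ph`.
#' @export
phagosome_ph <- function(ex440, ex480, phag_mask, cal) {
  p440 <- get_plane(if (dim(ex440)[3] > 1) project(ex440, "max") else ex440)
  p480 <- get_plane(if (dim(ex480)[3] > 1) project(ex480, "max") else ex480)
  ids <- phag_mask$label_ids
  ratio <- vapply(ids, function(pl) {
    sel <- phag_mask$labels == pl
    mean(p440[sel]) / mean(p480[sel])
  }, 0)
  data.frame(phagosome_id = ids, ratio = ratio,
             ph = ratio_to_ph(ratio, cal, quiet = TRUE))
}

#' Percent antigen remaining on ingested beads
#'
#' Antigen immunofluorescence of each cell-associated (ingested) bead,
#' expressed as a percentage of the mean fluorescence of beads not
#' associated with cells (free beads), on sum projections.
#'
#' @param img an [image_stack()]; z-stacks are sum-projected.
#' @param ingested_rois,free_rois data.frames with circular ROIs
#'   (`cx`, `cy`, `r` in pixels); at least one free bead required.
#' @return data.frame: one row per ingested bead with `percent_remaining`.
#' @export
antigen_remaining <- function(img, ingested_rois, free_rois) {
  stopifnot(inherits(img, "ImageStack"))
  if (is.null(free_rois) || nrow(free_rois) < 1)
    stop("at least one free-bead ROI is required")
  plane <- get_plane(if (dim(img)[3] > 1) project(img, "sum") else img)
  h <- nrow(plane); w <- ncol(plane)
  roi_mean <- function(cx, cy, r) {
    ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
    xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
    sub <- plane[ys, xs, drop = FALSE]
    dy <- outer(ys - cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cx)
    mean(sub[dy^2 + dx^2 <= r^2])
  }
  free_mean <- mean(vapply(seq_len(nrow(free_rois)), function(i)
    roi_mean(free_rois$cx[i], free_rois$cy[i], free_rois$r[i]), 0))
  if (free_mean <= 0) stop("zero free-bead mean fluorescence")
  ing <- vapply(seq_len(nrow(ingested_rois)), function(i)
    roi_mean(ingested_rois$cx[i], ingested_rois$cy[i], ingested_rois$r[i]), 0)
  data.frame(phagosome_id = seq_len(nrow(ingested_rois)),
             percent_remaining = 100 * ing / free_mean)
}
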