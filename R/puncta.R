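#' @keywords internal
# label connected above-threshold pixels inside a selection and return one
# row per component with centroid, area and mean intensity. `sel` is a
# logical matrix restricting the search region; thresholds are strict (>).
.components_above <- function(plane, sel, threshold, min_area_px,
                              connectivity = 8L) {
  bin <- sel & (plane > threshold)
  lm <- label_regions(bin, connectivity = connectivity)
  if (!length(lm$label_ids))
    return(data.frame(centroid_y = numeric(0), centroid_x = numeric(0),
                      area_px = integer(0), mean_intensity = numeric(0)))
  h <- nrow(plane)
  idx <- which(lm$labels > 0L)
  lab <- lm$labels[idx]
  ys <- (idx - 1L) %% h + 1L
  xs <- (idx - 1L) %/% h + 1L
  area <- as.integer(tapply(rep(1L, length(idx)), lab, sum))
  out <- data.frame(
    centroid_y = as.numeric(tapply(ys, lab, mean)),
    centroid_x = as.numeric(tapply(xs, lab, mean)),
    area_px = area,
    mean_intensity = as.numeric(tapply(plane[idx], lab, mean)))
  out[out$area_px >= min_area_px, , drop = FALSE]
}

#' Build a fixed-width ring outside each phagosome border
#'
#' For every phagosome label, the ring is the set of pixels outside the
#' phagosome whose Euclidean distance to the nearest phagosome pixel is at
#' most `width_um` (0.2 um, about 4 pixels at confocal scale). Rings keep
#' their phagosome's label; where rings of adjacent phagosomes would
#' overlap, each pixel goes to the nearer phagosome, so ring pixel sets are
#' disjoint.
#'
#' @param phagosome_mask a [label_mask()] with role `"phagosome"` and a
#'   known pixel size.
#' @param width_um ring width in micrometres (default 0.2).
#' @return a `LabelMask` with role `"ring"`.
#' @export
make_ring <- function(phagosome_mask, width_um = 0.2) {
  stopifnot(inherits(phagosome_mask, "LabelMask"))
  px <- phagosome_mask$pixel_size_nm
  if (is.na(px)) stop("phagosome mask needs a pixel size")
  width_px <- width_um * 1000 / px
  if (width_px < 1) stop("ring width is below one pixel")
  nr <- nearest_region(phagosome_mask$labels, width_px)
  ring <- nr$label
  ring[!(nr$dist > 0 & nr$dist <= width_px)] <- 0L
  label_mask(ring, role = "ring", pixel_size_nm = px)
}

#' Detect puncta in periphagosomal rings
#'
#' Connected components of above-threshold ring pixels whose area exceeds
#' `min_area_um2` (strict, i.e. at least 5 pixels at 50 nm pitch) count as
#' puncta; a per-phagosome count is returned. The reproducible substitute
#' for a manually-defined per-cell threshold is `"auto"`: cytosolic mean
#' plus two cytosolic standard deviations, where the cytosol is the cell
#' minus its phagosomes and rings. Multi-plane stacks are max-projected
#' first.
#'
#' @param img an [image_stack()] (channel 1, frame 1 analysed).
#' @param ring ring mask from [make_ring()].
#' @param threshold `"auto"` or a numeric intensity.
#' @param min_area_um2 minimum punctum area (default 0.01 um^2, strict >).
#' @param cell_mask,phagosome_mask optional masks refining the cytosol used
#'   by the auto threshold (per-cell when `cell_mask` is given).
#' @param connectivity component connectivity (default 8).
#' @return an object of class `PunctaSet`: data.frame `puncta` (phagosome,
#'   centroid, area, mean intensity), named per-phagosome `counts`, and
#'   `source_region = "ring"`.
#' @export
detect_ring_puncta <- function(img, ring, threshold = "auto",
                               min_area_um2 = 0.01, cell_mask = NULL,
                               phagosome_mask = NULL, connectivity = 8L) {
  stopifnot(inherits(img, "ImageStack"), inherits(ring, "LabelMask"))
  if (dim(img)[3] > 1) img <- project(img, "max")
  plane <- get_plane(img)
  if (!all(dim(plane) == dim(ring$labels)))
    stop("ring mask is not aligned to the image")
  px_um2 <- (img$pixel_size_nm / 1000)^2
  min_area_px <- floor(min_area_um2 / px_um2 + 1e-9) + 1L  # strict > in um^2
  cyto <- ring$labels == 0L
  if (!is.null(phagosome_mask)) cyto <- cyto & phagosome_mask$labels == 0L
  if (!is.null(cell_mask)) cyto <- cyto & cell_mask$labels > 0L
  # per-cell auto thresholds (global when no cell mask)
  thr_for <- function(lab) {
    if (is.numeric(threshold)) return(threshold)
    if (!identical(threshold, "auto")) stop("threshold must be numeric or 'auto'")
    sel <- cyto
    if (!is.null(cell_mask) && !is.null(phagosome_mask)) {
      inph <- phagosome_mask$labels == lab
      if (any(inph)) {
        cl <- cell_mask$labels[inph]
        cl <- as.integer(names(which.max(table(cl[cl > 0L]))))
        if (length(cl)) sel <- cyto & cell_mask$labels == cl
      }
    }
    if (!any(sel)) stop("empty cytosol region for auto threshold")
    mean(plane[sel]) + 2 * stats::sd(plane[sel])
  }
  ids <- ring$label_ids
  if (!length(ids)) warning("ring mask is empty; zero puncta reported")
  rows <- list()
  counts <- stats::setNames(integer(length(ids)), ids)
  for (lab in ids) {
    comp <- .components_above(plane, ring$labels == lab, thr_for(lab),
                              min_area_px, connectivity)
    counts[as.character(lab)] <- nrow(comp)
    if (nrow(comp)) {
      comp$phagosome_id <- lab
      rows[[length(rows) + 1L]] <- comp
    }
  }
  puncta <- if (length(rows)) do.call(rbind, rows) else
    data.frame(centroid_y = numeric(0), centroid_x = numeric(0),
               area_px = integer(0), mean_intensity = numeric(0),
               phagosome_id = integer(0))
  puncta$area_um2 <- puncta$area_px * px_um2
  structure(list(puncta = puncta, counts = counts, source_region = "ring"),
            class = "PunctaSet")
}

#' @export
print.PunctaSet <- function(x, ...) {
  cat(sprintf("PunctaSet (%s): %d puncta over %d region(s)\n",
              x$source_region, nrow(x$puncta), length(x$counts)))
  invisible(x)
}

#' Per-condition recruitment summary with bootstrap contrasts
#'
#' Mean, SEM and n of per-phagosome puncta counts for each scenario, plus
#' the percent change of every scenario against a named reference with a
#' seeded bootstrap 95% CI.
#'
#' @param counts_by_scenario named list of per-phagosome count vectors.
#' @param reference name of the reference scenario (default: first).
#' @param n_boot bootstrap resamples (default 1e4).
#' @param seed bootstrap seed.
#' @return list of class `RecruitmentSummary`: `table` (a
#'   [summary_table()]) and `contrasts` data.frame with `pct_change`,
#'   `ci_lo`, `ci_hi` vs the reference.
#' @export
recruitment_summary <- function(counts_by_scenario,
                                reference = names(counts_by_scenario)[1],
                                n_boot = 1e4, seed = 1L) {
  stopifnot(length(counts_by_scenario) >= 1)
  if (!reference %in% names(counts_by_scenario))
    stop("reference scenario '", reference, "' absent")
  tabs <- lapply(names(counts_by_scenario), function(s) {
    v <- counts_by_scenario[[s]]
    summary_table(scenario = s,
                  metric = c("mean_count", "sem_count", "n"),
                  value = c(mean(v), stats::sd(v) / sqrt(length(v)), length(v)),
                  units = c("puncta/phagosome", "puncta/phagosome", "phagosomes"))
  })
  others <- setdiff(names(counts_by_scenario), reference)
  contrasts <- do.call(rbind, lapply(seq_along(others), function(i) {
    s <- others[i]
    b <- bootstrap_pct_change(counts_by_scenario[[reference]],
                              counts_by_scenario[[s]],
                              n_boot = n_boot, seed = seed + i)
    data.frame(scenario = s, reference = reference,
               pct_change = b$pct_change, ci_lo = b$ci[1], ci_hi = b$ci[2])
  }))
  structure(list(table = do.call(bind_summary, tabs), contrasts = contrasts),
            class = "RecruitmentSummary")
}

#' @export
print.RecruitmentSummary <- function(x, ...) {
  print(as.data.frame(x$table))
  if (!is.null(x$contrasts) && nrow(x$contrasts)) {
    cat("contrasts vs", x$contrasts$reference[1], ":\n")
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}
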