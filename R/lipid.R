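#' Per-phagosome enrichment track
#'
#' Phospholipid-probe enrichment over time for one phagosome: E(t) is the
#' phagosomal mean fluorescence divided by the initial whole-cell mean
#' fluorescence, minus 1, so E = 0 means phagosome at cell-average level
#' and E >= -1 always (fluorescence is non-negative).
#'
#' @param phagosome_id identifier.
#' @param t_min minutes since ingestion start.
#' @param E enrichment values.
#' @return an object of class `Track`.
#' @export
lipid_track <- function(phagosome_id, t_min, E) {
  stopifnot(length(t_min) == length(E))
  if (any(E < -1 - 1e-9)) stop("enrichment below -1 is impossible")
  structure(list(phagosome_id = phagosome_id, t_min = as.numeric(t_min),
                 E = as.numeric(E)), class = "Track")
}

#' @export
print.Track <- function(x, ...) {
  cat(sprintf("Track (phagosome %s): %d samples over %.0f min\n",
              as.character(x$phagosome_id), length(x$t_min), max(x$t_min)))
  invisible(x)
}

#' Enrichment tracks from a rendered time-lapse
#'
#' E(t) = mean phagosomal intensity at frame t divided by the mean
#' whole-cell intensity at the first analysed frame, minus 1, computed on
#' max projections of each frame's z-stack. The initial-cell normaliser is
#' taken per cell (the cell containing the phagosome).
#'
#' @param stack an [image_stack()] (1 frame/min in the reference
#'   protocol).
#' @param phag_mask a phagosome [label_mask()], or a list of masks (one
#'   per frame) when phagosomes move.
#' @param cell_mask cell [label_mask()].
#' @param ingestion_start_frame first analysed frame (time zero).
#' @return list of [lipid_track()]s, one per phagosome label.
#' @export
enrichment_track <- function(stack, phag_mask, cell_mask,
                             ingestion_start_frame = 1L) {
  stopifnot(inherits(stack, "ImageStack"), inherits(cell_mask, "LabelMask"))
  if (dim(stack)[3] > 1) stack <- project(stack, "max")
  n_t <- dim(stack)[2]
  frames <- ingestion_start_frame:n_t
  per_frame <- inherits(phag_mask, "LabelMask") == FALSE
  mask0 <- if (per_frame) phag_mask[[ingestion_start_frame]] else phag_mask
  ids <- mask0$label_ids
  dt_min <- if (stack$frame_interval_s > 0) stack$frame_interval_s / 60 else 1
  # phagosome -> cell mapping and per-cell initial normaliser
  p0 <- get_plane(stack, frame = ingestion_start_frame)
  cell_of <- vapply(ids, function(pl) {
    cl <- cell_mask$labels[mask0$labels == pl]
    cl <- cl[cl > 0L]
    if (!length(cl)) return(NA_integer_)
    as.integer(names(which.max(table(cl))))
  }, 0L)
  init <- vapply(ids, function(pl) {
    cl <- cell_of[match(pl, ids)]
    sel <- if (is.na(cl)) cell_mask$labels > 0L else cell_mask$labels == cl
    mean(p0[sel])
  }, 0)
  if (any(init <= 0)) stop("zero initial cell fluorescence")
  # grouped phagosome means per frame (vectorised; static-mask fast path)
  phag_means <- matrix(NA_real_, length(frames), length(ids))
  if (!per_frame) {
    idx <- which(phag_mask$labels > 0L)
    grp <- factor(phag_mask$labels[idx], levels = ids)
    npx <- as.vector(table(grp))
    for (i in seq_along(frames)) {
      v <- get_plane(stack, frame = frames[i])[idx]
      phag_means[i, ] <- rowsum(v, grp)[, 1] / npx
    }
  } else {
    for (i in seq_along(frames)) {
      m <- phag_mask[[frames[i]]]
      pl <- get_plane(stack, frame = frames[i])
      for (k in seq_along(ids))
        phag_means[i, k] <- mean(pl[m$labels == ids[k]])
    }
  }
  lapply(seq_along(ids), function(k) {
    lipid_track(ids[k], t_min = (frames - ingestion_start_frame) * dt_min,
                E = phag_means[, k] / init[k] - 1)
  })
}

#' Peak and window statistics of an enrichment track
#'
#' The initial peak is the global maximum of E within the first
#' `peak_search_min` minutes after ingestion (the probe influx peak occurs
#' promptly after ingestion). Named windows are averaged with their
#' declared anchoring: `"ingestion"` windows are (start, end) minutes after
#' time zero; `"peak"` windows are relative to the detected peak time.
#'
#' @param track a [lipid_track()].
#' @param windows named list; each element `list(start =, end =, anchor =
#'   "ingestion"|"peak")` in minutes.
#' @param peak_search_min peak search horizon (default 10 min).
#' @return a [summary_table()] with `peak_E`, `peak_time_min` and one
#'   `window_mean_<name>` row per window (NA + flag when a window falls
#'   outside coverage).
#' @export
window_stats <- function(track, windows = list(), peak_search_min = 10) {
  stopifnot(inherits(track, "Track"))
  sel <- track$t_min <= peak_search_min
  peak_E <- max(track$E[sel])
  peak_t <- track$t_min[sel][which.max(track$E[sel])]
  metrics <- c(peak_E = peak_E, peak_time_min = peak_t)
  units <- c("enrichment", "min")
  for (nm in names(windows)) {
    wdef <- windows[[nm]]
    anchor <- if (is.null(wdef$anchor)) "ingestion" else wdef$anchor
    lo <- wdef$start + if (anchor == "peak") peak_t else 0
    hi <- wdef$end + if (anchor == "peak") peak_t else 0
    inw <- track$t_min >= lo & track$t_min <= hi
    v <- if (hi > max(track$t_min) + 1e-9 || !any(inw)) NA_real_ else
      mean(track$E[inw])
    metrics[paste0("window_mean_", nm)] <- v
    units <- c(units, "enrichment")
  }
  tab <- summary_table(phagosome_id = track$phagosome_id,
                       metric = names(metrics), value = unname(metrics),
                       units = units)
  tab
}

# extract a per-track scalar metric from a list of tracks
.track_metric <- function(tracks, metric, windows, peak_search_min = 10) {
  vapply(tracks, function(tr) {
    st <- window_stats(tr, windows, peak_search_min)
    v <- st$value[st$metric == metric]
    if (!length(v)) stop("metric '", metric, "' not produced by window_stats")
    v
  }, 0)
}

#' Condition contrast of a track metric
#'
#' Per scenario, the mean and SEM of a per-track metric (a window mean, the
#' peak, or any [window_stats()] row), and for every non-reference scenario
#' the fold change and percent change versus the reference with a seeded
#' bootstrap 95% CI.
#'
#' @param groups named list: scenario -> list of [lipid_track()]s, or
#'   scenario -> numeric vector of ready-made per-track metric values.
#' @param metric metric name as produced by [window_stats()] (e.g.
#'   `"window_mean_postpeak"`, `"peak_E"`); ignored for numeric groups.
#' @param reference reference scenario name.
#' @param windows window definitions passed to [window_stats()].
#' @param n_boot,seed bootstrap settings.
#' @return list of class `ConditionContrast`: `table` (means/SEM/n) and
#'   `contrasts` data.frame (`fold_change`, `pct_change`, `ci_lo`,
#'   `ci_hi`).
#' @export
condition_contrast <- function(groups, metric = NULL,
                               reference = names(groups)[1],
                               windows = list(), n_boot = 1e4, seed = 1L) {
  stopifnot(length(groups) >= 1)
  if (!reference %in% names(groups))
    stop("reference scenario '", reference, "' absent")
  vals <- lapply(groups, function(g) {
    v <- if (is.numeric(g)) g else .track_metric(g, metric, windows)
    v[is.finite(v)]  # tracks whose window fell outside coverage are flagged NA
  })
  if (any(vapply(vals, length, 0L) == 0)) stop("empty group")
  tabs <- lapply(names(vals), function(s) {
    v <- vals[[s]]
    summary_table(scenario = s, metric = c("mean", "sem", "n"),
                  value = c(mean(v), stats::sd(v) / sqrt(length(v)), length(v)),
                  units = c("metric", "metric", "tracks"))
  })
  others <- setdiff(names(vals), reference)
  contrasts <- do.call(rbind, lapply(seq_along(others), function(i) {
    s <- others[i]
    b <- bootstrap_pct_change(vals[[reference]], vals[[s]],
                              n_boot = n_boot, seed = seed + i)
    data.frame(scenario = s, reference = reference,
               fold_change = mean(vals[[s]]) / mean(vals[[reference]]),
               pct_change = b$pct_change, ci_lo = b$ci[1], ci_hi = b$ci[2])
  }))
  structure(list(table = do.call(bind_summary, tabs), contrasts = contrasts),
            class = "ConditionContrast")
}

#' @export
print.ConditionContrast <- function(x, ...) {
  print(as.data.frame(x$table))
  if (!is.null(x$contrasts) && nrow(x$contrasts)) {
    cat("contrasts vs", x$contrasts$reference[1], ":\n")
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}

#' Standard lipid analysis windows
#'
#' The three windows behind the published contrasts: `postpeak` = 5-25 min
#' after the initial peak (peak-anchored), `early` = 5-10 min after
#' ingestion, `full` = the whole observation (0-30 min).
#'
#' @param duration_min observation length (default 30).
#' @return named window list for [window_stats()].
#' @export
lipid_windows <- function(duration_min = 30) {
  list(postpeak = list(start = 5, end = 25, anchor = "peak"),
       early = list(start = 5, end = 10, anchor = "ingestion"),
       full = list(start = 0, end = duration_min, anchor = "ingestion"))
}
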