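#' EM cross-section profile of a phagosome
#'
#' One transmission-EM cross-section: the phagosome boundary (a circle or a
#' simple closed polygon, nm coordinates) plus ER membranes abstracted as
#' open polylines (cisterna midlines). Contact-site detection is a distance
#' criterion on these curves; EM texture classification is out of scope.
#'
#' @param boundary either `list(type = "circle", center = c(x, y),
#'   radius_nm = r)` or an n x 2 matrix of polygon vertices (closed
#'   implicitly).
#' @param er_segments list of n x 2 matrices, open polylines in nm.
#' @param phagosome_diameter_nm cross-section diameter; must agree with the
#'   boundary extent within 1%.
#' @param phagosome_id optional identifier.
#' @return an object of class `EMProfile`.
#' @export
em_profile <- function(boundary, er_segments = list(),
                       phagosome_diameter_nm = NULL, phagosome_id = NA_integer_) {
  if (is.matrix(boundary)) {
    ext <- max(dist(boundary))
    bnd <- list(type = "polygon", vertices = boundary)
  } else if (is.list(boundary) && identical(boundary$type, "circle")) {
    ext <- 2 * boundary$radius_nm
    bnd <- boundary
  } else stop("boundary must be a circle spec or a vertex matrix")
  if (is.null(phagosome_diameter_nm)) phagosome_diameter_nm <- ext
  if (abs(phagosome_diameter_nm - ext) > 0.01 * phagosome_diameter_nm)
    stop("declared diameter inconsistent with boundary extent (>1%)")
  stopifnot(is.list(er_segments))
  structure(list(boundary = bnd, er_segments = er_segments,
                 phagosome_diameter_nm = phagosome_diameter_nm,
                 phagosome_id = as.integer(phagosome_id)),
            class = "EMProfile")
}

#' @export
print.EMProfile <- function(x, ...) {
  cat(sprintf("EMProfile: diameter %.0f nm, %d ER segment(s)\n",
              x$phagosome_diameter_nm, length(x$er_segments)))
  invisible(x)
}

# nearest distance from each row of pts (n x 2) to the boundary curve
.boundary_gap <- function(pts, boundary) {
  if (identical(boundary$type, "circle")) {
    abs(sqrt((pts[, 1] - boundary$center[1])^2 +
             (pts[, 2] - boundary$center[2])^2) - boundary$radius_nm)
  } else {
    v <- boundary$vertices
    p1 <- v
    p2 <- v[c(2:nrow(v), 1), , drop = FALSE]
    d <- rep(Inf, nrow(pts))
    for (s in seq_len(nrow(p1))) {
      ax <- p1[s, 1]; ay <- p1[s, 2]
      bx <- p2[s, 1] - ax; by <- p2[s, 2] - ay
      len2 <- bx^2 + by^2
      t <- if (len2 == 0) rep(0, nrow(pts)) else
        pmin(1, pmax(0, ((pts[, 1] - ax) * bx + (pts[, 2] - ay) * by) / len2))
      ds <- sqrt((pts[, 1] - (ax + t * bx))^2 + (pts[, 2] - (ay + t * by))^2)
      d <- pmin(d, ds)
    }
    d
  }
}

# resample an open polyline at `step` spacing along its length; returns
# points and their arc positions
.resample_polyline <- function(poly, step = 1) {
  seg <- diff(poly)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (total == 0) return(NULL)
  s <- unique(c(seq(0, total, by = step), total))
  cum <- c(0, cumsum(seg_len))
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg_len))
  frac <- (s - cum[idx]) / seg_len[idx]
  frac[!is.finite(frac)] <- 0
  pts <- poly[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  list(pts = pts, s = s)
}

#' Detect ER-phagosome membrane contacts on an EM profile
#'
#' Samples every ER polyline at `step_nm` spacing and returns the maximal
#' contiguous sub-arcs whose every sampled point lies within `gap_max_nm`
#' of the phagosome boundary (membranes within 30 nm count as a contact
#' site). Sub-arcs shorter than `min_run_nm` are discarded as grazing
#' artifacts; arc length is measured along the ER polyline.
#'
#' @param profile an [em_profile()].
#' @param gap_max_nm membrane-to-membrane distance criterion (default 30).
#' @param min_run_nm minimum contact run length kept (default 20, about one
#'   EM section thickness).
#' @param step_nm sampling step along each polyline (default 1, the manual
#'   caliper granularity).
#' @return an object of class `ContactSet`: data.frame `contacts` with
#'   columns `segment_id`, `arc_length_nm`, `min_gap_nm`, plus
#'   `phagosome_id`.
#' @export
detect_contacts <- function(profile, gap_max_nm = 30, min_run_nm = 20,
                            step_nm = 1) {
  stopifnot(inherits(profile, "EMProfile"), gap_max_nm > 0)
  out <- list()
  for (i in seq_along(profile$er_segments)) {
    rs <- .resample_polyline(profile$er_segments[[i]], step_nm)
    if (is.null(rs)) {
      warning("degenerate zero-length ER polyline skipped (segment ", i, ")")
      next
    }
    gap <- .boundary_gap(rs$pts, profile$boundary)
    inside <- gap <= gap_max_nm
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- rs$s[ends[k]] - rs$s[starts[k]]
      if (len >= min_run_nm) {
        out[[length(out) + 1L]] <- data.frame(
          segment_id = i, arc_length_nm = len,
          min_gap_nm = min(gap[starts[k]:ends[k]]))
      }
    }
  }
  contacts <- if (length(out)) do.call(rbind, out) else
    data.frame(segment_id = integer(0), arc_length_nm = numeric(0),
               min_gap_nm = numeric(0))
  structure(list(contacts = contacts, phagosome_id = profile$phagosome_id),
            class = "ContactSet")
}

#' @export
print.ContactSet <- function(x, ...) {
  cat(sprintf("ContactSet: %d contact(s)\n", nrow(x$contacts)))
  invisible(x)
}

#' Retain phagosome cross-sections larger than a diameter threshold
#'
#' Only slices with a cross-section of more than `min_diameter_um` (strict)
#' are analysed, avoiding tangential cuts near the phagosome pole.
#'
#' @param profiles list of [em_profile()]s.
#' @param min_diameter_um threshold in micrometres (default 1).
#' @return the retained profiles, order preserved.
#' @export
filter_profiles <- function(profiles, min_diameter_um = 1.0) {
  keep <- vapply(profiles, function(p)
    p$phagosome_diameter_nm > min_diameter_um * 1000, TRUE)
  profiles[keep]
}

#' Contact-set summary statistics
#'
#' Per-condition descriptives of a set of phagosome contact profiles: mean
#' contacts per phagosome, median and mean individual contact length, the
#' fraction of contacts longer than `large_nm`, and the pooled length list.
#'
#' @param sets list of `ContactSet`s (one per phagosome).
#' @param large_nm very-large-contact threshold, nm (default 400).
#' @param scenario label used in the output table.
#' @return list of class `ContactStats`: `counts`, `mean_count`, pooled
#'   `lengths`, `median_length`, `mean_length`, `frac_large`,
#'   `n_phagosomes`, and `table` (a [summary_table()]).
#' @export
contact_stats <- function(sets, large_nm = 400, scenario = NA_character_) {
  stopifnot(length(sets) >= 1)
  counts <- vapply(sets, function(s) nrow(s$contacts), 0L)
  lengths <- unlist(lapply(sets, function(s) s$contacts$arc_length_nm))
  has_len <- length(lengths) > 0
  res <- list(
    counts = counts,
    mean_count = mean(counts),
    lengths = if (has_len) lengths else numeric(0),
    median_length = if (has_len) stats::median(lengths) else NA_real_,
    mean_length = if (has_len) mean(lengths) else NA_real_,
    frac_large = if (has_len) mean(lengths > large_nm) else NA_real_,
    n_phagosomes = length(sets))
  res$table <- summary_table(
    scenario = scenario,
    metric = c("mean_contacts_per_phagosome", "median_contact_length",
               "mean_contact_length", "frac_contacts_large"),
    value = c(res$mean_count, res$median_length, res$mean_length,
              res$frac_large),
    units = c("contacts/phagosome", "nm", "nm", "fraction"))
  class(res) <- "ContactStats"
  res
}

#' @export
print.ContactStats <- function(x, ...) {
  cat(sprintf(
    "ContactStats: %d phagosomes, %.2f contacts/phagosome, median length %.1f nm, %.1f%% > large threshold\n",
    x$n_phagosomes, x$mean_count, x$median_length, 100 * x$frac_large))
  invisible(x)
}

#' Two-sided F-test for equality of variances of contact lengths
#'
#' F is the ratio of the larger to the smaller sample variance (n - 1
#' denominators); the two-sided p-value is twice the upper tail of the F
#' distribution with matching degrees of freedom, capped at 1. Used for
#' the greater-diversity-of-contact-lengths comparison; all other group
#' comparisons are reported descriptively.
#'
#' @param lengths_a,lengths_b numeric vectors with >= 2 values and nonzero
#'   variance each.
#' @return list with `F`, `p`, `df` (numerator, denominator dfs).
#' @export
variance_f_test <- function(lengths_a, lengths_b) {
  if (length(lengths_a) < 2 || length(lengths_b) < 2)
    stop("each group needs at least 2 values")
  va <- stats::var(lengths_a); vb <- stats::var(lengths_b)
  if (va == 0 || vb == 0) stop("zero variance in a group")
  if (va >= vb) {
    F <- va / vb; df <- c(length(lengths_a) - 1L, length(lengths_b) - 1L)
  } else {
    F <- vb / va; df <- c(length(lengths_b) - 1L, length(lengths_a) - 1L)
  }
  p <- min(1, 2 * stats::pf(F, df[1], df[2], lower.tail = FALSE))
  list(F = F, p = p, df = df)
}
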