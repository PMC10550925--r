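#' Integer-labelled region mask
#'
#' A `LabelMask` holds integer-labelled regions (cells, phagosomes, cytosol,
#' rings, beads) on a 2-D grid aligned to an [image_stack()] plane. Label 0
#' is background; region labels are positive and disjoint by construction.
#'
#' @param labels integer matrix (y, x); 0 = background.
#' @param role one of `"cell"`, `"phagosome"`, `"cytosol"`, `"ring"`,
#'   `"bead_ingested"`, `"bead_free"`.
#' @param pixel_size_nm physical pixel pitch, nm.
#' @return an object of class `LabelMask`.
#' @export
label_mask <- function(labels, role = c("cell", "phagosome", "cytosol",
                                        "ring", "bead_ingested", "bead_free"),
                       pixel_size_nm = NA_real_) {
  role <- match.arg(role)
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be >= 0")
  ids <- sort(unique(labels[labels > 0L]))
  structure(list(labels = labels, role = role,
                 label_ids = as.integer(ids),
                 pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  cat(sprintf("LabelMask (%s): %d x %d px, %d region(s)\n",
              x$role, nrow(x$labels), ncol(x$labels), length(x$label_ids)))
  invisible(x)
}

# neighbour offsets (dy, dx) for 4- or 8-connectivity
.conn_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    cbind(dy = c(-1L, 1L, 0L, 0L), dx = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8L) {
    cbind(dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else stop("connectivity must be 4 or 8")
}

#' Connected-component labelling
#'
#' Labels maximal connected components of a binary grid, the primitive
#' behind every "Analyze particles"-style step (puncta, hotspots). The
#' labelling order is deterministic: components are numbered 1..n by the
#' raster-scan position (top-to-bottom, then left-to-right) of their first
#' pixel.
#'
#' @param binary logical matrix.
#' @param connectivity 4 or 8 (default 8, the ImageJ particle-analysis
#'   convention).
#' @param role,pixel_size_nm passed to [label_mask()].
#' @return a `LabelMask` with components labelled 1..n.
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1] <- m[2, 2] <- TRUE
#' length(label_regions(m, 4)$label_ids)  # 2: diagonal pixels separate
#' length(label_regions(m, 8)$label_ids)  # 1
#' @export
label_regions <- function(binary, connectivity = 8L, role = "cell",
                          pixel_size_nm = NA_real_) {
  if (!is.matrix(binary) || !is.logical(binary))
    stop("`binary` must be a logical matrix")
  connectivity <- as.integer(connectivity)
  nb <- .conn_offsets(connectivity)
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  # raster order over foreground pixels: sort linear (column-major) indices
  # by (y, x), i.e. by row first
  fg <- which(binary)
  if (length(fg)) {
    ys <- (fg - 1L) %% h + 1L
    xs <- (fg - 1L) %/% h + 1L
    fg <- fg[order(ys, xs)]
  }
  nxt <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    nxt <- nxt + 1L
    lab[seed] <- nxt
    frontier <- seed
    while (length(frontier)) {
      y <- (frontier - 1L) %% h + 1L
      x <- (frontier - 1L) %/% h + 1L
      nxt_frontier <- integer(0)
      for (k in seq_len(nrow(nb))) {
        ny <- y + nb[k, 1L]; nx <- x + nb[k, 2L]
        ok <- ny >= 1L & ny <= h & nx >= 1L & nx <= w
        if (!any(ok)) next
        idx <- (nx[ok] - 1L) * h + ny[ok]
        idx <- idx[binary[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- nxt
          nxt_frontier <- c(nxt_frontier, idx)
        }
      }
      frontier <- unique(nxt_frontier)
    }
  }
  label_mask(lab, role = role, pixel_size_nm = pixel_size_nm)
}

# shift matrix content by (dy, dx); result[y, x] = m[y - dy, x - dx],
# vacated cells filled with `fill`
.shift_mat <- function(m, dy, dx, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1L, 1L + dy):min(h, h + dy)
  xs <- max(1L, 1L + dx):min(w, w + dx)
  if (dy > h || dy < -h || dx > w || dx < -w) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

#' Bounded Euclidean distance / nearest-label transform
#'
#' For every pixel within `max_px` (Euclidean, pixel centres) of a labelled
#' region, returns the distance to the nearest region pixel and that
#' region's label. Pixels farther than `max_px` get distance `Inf` and
#' label 0. Exact within the search radius: all integer offsets with
#' |offset| <= max_px are scanned in increasing distance order, so the
#' first hit is the nearest (ties broken deterministically by offset
#' order).
#'
#' @param labels integer matrix of region labels (0 = background).
#' @param max_px search radius in pixels.
#' @return list with matrices `dist` and `label`.
#' @export
nearest_region <- function(labels, max_px) {
  stopifnot(is.matrix(labels), max_px >= 0)
  r <- ceiling(max_px)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off$d <- sqrt(off$dy^2 + off$dx^2)
  off <- off[off$d <= max_px + 1e-9, , drop = FALSE]
  off <- off[order(off$d, off$dy, off$dx), , drop = FALSE]
  h <- nrow(labels); w <- ncol(labels)
  dist <- matrix(Inf, h, w)
  lab <- matrix(0L, h, w)
  for (k in seq_len(nrow(off))) {
    # candidate label seen from pixel p at offset (dy,dx): labels[p + off]
    cand <- .shift_mat(labels, -off$dy[k], -off$dx[k], fill = 0L)
    sel <- lab == 0L & cand > 0L
    if (any(sel)) {
      lab[sel] <- cand[sel]
      dist[sel] <- off$d[k]
    }
  }
  list(dist = dist, label = lab)
}
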