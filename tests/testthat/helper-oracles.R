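# Independent brute-force oracles used to validate the detectors. These are
# deliberately naive implementations (explicit stacks and loops) sharing no
# code with the package internals.

# flood-fill connected components; returns label matrix and count
flood_fill_oracle <- function(binary, connectivity = 8L) {
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  if (connectivity == 4L) {
    nb <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    nb <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
               c(1, -1), c(1, 0), c(1, 1))
  }
  cur <- 0L
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!binary[y, x] || lab[y, x] != 0L) next
    cur <- cur + 1L
    stack <- list(c(y, x))
    lab[y, x] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in nb) {
        ny <- p[1] + d[1]; nx <- p[2] + d[2]
        if (ny >= 1 && ny <= h && nx >= 1 && nx <= w &&
            binary[ny, nx] && lab[ny, nx] == 0L) {
          lab[ny, nx] <- cur
          stack[[length(stack) + 1L]] <- c(ny, nx)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# brute-force puncta counter: pixel scan + flood fill + area filter.
# keep_rule: "ge" keeps area >= min_area, "gt" keeps area > min_area.
puncta_oracle <- function(plane, sel, threshold, min_area,
                          connectivity = 8L, keep_rule = "ge") {
  bin <- sel & (plane > threshold)
  ff <- flood_fill_oracle(bin, connectivity)
  if (ff$n == 0) return(list(count = 0L, areas = integer(0)))
  areas <- as.integer(table(ff$labels[ff$labels > 0]))
  keep <- if (keep_rule == "ge") areas >= min_area else areas > min_area
  list(count = sum(keep), areas = areas[keep])
}

# brute-force contact detector for circle-boundary EM profiles: walk each
# polyline in 1 nm steps using linear interpolation, threshold the gap,
# merge runs
contact_oracle <- function(profile, gap_max_nm = 30, min_run_nm = 20) {
  stopifnot(identical(profile$boundary$type, "circle"))
  ctr <- profile$boundary$center; R <- profile$boundary$radius_nm
  lens <- numeric(0)
  for (poly in profile$er_segments) {
    seg_len <- sqrt(rowSums(diff(poly)^2))
    total <- sum(seg_len)
    if (total == 0) next
    s_grid <- unique(c(seq(0, total, by = 1), total))
    cum <- c(0, cumsum(seg_len))
    px <- stats::approx(cum, poly[, 1], xout = s_grid)$y
    py <- stats::approx(cum, poly[, 2], xout = s_grid)$y
    gap <- abs(sqrt((px - ctr[1])^2 + (py - ctr[2])^2) - R)
    inside <- gap <= gap_max_nm
    i <- 1L
    while (i <= length(inside)) {
      if (inside[i]) {
        j <- i
        while (j < length(inside) && inside[j + 1L]) j <- j + 1L
        run <- s_grid[j] - s_grid[i]
        if (run >= min_run_nm) lens <- c(lens, run)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  list(count = length(lens), lengths = lens)
}

# quick scenario helper
preset <- function(assay, condition, seed = 1L) {
  scenario_preset(assay, condition, seed = seed)
}
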