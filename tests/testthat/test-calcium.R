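# Fura-2 ratio traces, SOCE metrics, Fluo-8 hotspot detection

test_that("fura_ratio divides per-cell channel means and flags zero frames", {
  cellm <- matrix(0L, 10, 10); cellm[3:8, 3:8] <- 1L
  cells <- label_mask(cellm, "cell", 250)
  arr380 <- array(runif(3 * 100, 10, 20), c(1, 3, 1, 10, 10))
  f380 <- image_stack(arr380, pixel_size_nm = 250, frame_interval_s = 3)
  f340 <- image_stack(2 * arr380, pixel_size_nm = 250, frame_interval_s = 3)
  tr <- fura_ratio(f340, f380, cells, readd_time_s = 3)[[1]]
  expect_equal(tr$ratio, rep(2, 3))
  expect_equal(tr$t_s, c(0, 3, 6))

  # changing pixels outside the cell leaves the ratio untouched
  f340b <- f340; f340b$data[1, , , 1, 1] <- 999
  expect_equal(fura_ratio(f340b, f380, cells)[[1]]$ratio, tr$ratio)

  # zero-denominator frame flagged invalid, not dropped
  f380z <- f380; f380z$data[1, 2, 1, , ] <- 0
  trz <- fura_ratio(f340, f380z, cells)[[1]]
  expect_false(trz$valid[2])
  expect_true(all(trz$valid[c(1, 3)]))
})

test_that("soce_metrics recovers amplitude and slope of constructed traces", {
  t <- seq(0, 600, by = 3)
  # constant trace -> (0, 0)
  flat <- ratio_trace(t, rep(0.5, length(t)), readd_time_s = 300)
  m0 <- soce_metrics(flat, baseline_window_s = 60)
  expect_equal(m0$max_slope, 0)
  expect_equal(m0$peak_amplitude, 0)

  # linear ramp 0.01/s to a plateau +0.8 after re-addition
  r <- rep(0.5, length(t))
  post <- t >= 300
  r[post] <- 0.5 + pmin(0.01 * (t[post] - 300), 0.8)
  ramp <- ratio_trace(t, r, readd_time_s = 300)
  m1 <- soce_metrics(ramp, baseline_window_s = 60)
  expect_equal(m1$peak_amplitude, 0.8, tolerance = 1e-9)
  expect_equal(m1$max_slope, 0.01, tolerance = 1e-9)

  # amplitude invariant under a constant offset
  m2 <- soce_metrics(ratio_trace(t, r + 1.3, readd_time_s = 300),
                     baseline_window_s = 60)
  expect_equal(m2$peak_amplitude, m1$peak_amplitude)

  expect_error(soce_metrics(ratio_trace(t, r, readd_time_s = 1e4),
                            baseline_window_s = 60), "inside the trace")
})

test_that("generated SOCE traces recover the configured amplitude and contrast", {
  g <- gen_fura_traces(preset("fura", "shCTR", seed = 3), 40)
  amp <- vapply(g$traces, function(tr)
    soce_metrics(tr, baseline_window_s = 30)$peak_amplitude, 0)
  expect_equal(mean(amp), mean(g$truth$amplitude), tolerance = 0.05)

  g2 <- gen_fura_traces(preset("fura", "shSec22b", seed = 3), 40)
  amp2 <- vapply(g2$traces, function(tr)
    soce_metrics(tr, baseline_window_s = 30)$peak_amplitude, 0)
  # knockdown arm shows the configured increase in peak amplitude
  expect_gt(mean(amp2), mean(amp))
  expect_equal(mean(amp2) / mean(amp), 0.95 / 0.8, tolerance = 0.05)
})

test_that("detect_hotspots implements the threshold, area and distance rules", {
  # uniform image -> no hotspots (ties fall below the strict threshold)
  cellm <- matrix(1L, 40, 40)
  phagm <- matrix(0L, 40, 40); phagm[18:22, 18:22] <- 1L
  cytom <- cellm; cytom[12:28, 12:28] <- 0L
  uni <- image_stack(matrix(50, 40, 40), pixel_size_nm = 250)
  hs0 <- detect_hotspots(uni, label_mask(cytom, "cytosol", 250),
                         label_mask(phagm, "phagosome", 250))
  expect_equal(nrow(hs0$hotspots), 0)

  # one 2x2 block at mu + 3 sd, 2 px from the border -> exactly 1 hotspot
  set.seed(91)
  pl <- matrix(rnorm(1600, 50, 2), 40, 40)
  pl[19:20, 24:25] <- 50 + 3 * 2   # phagosome right edge is column 22
  img <- image_stack(pl, pixel_size_nm = 250)
  hs1 <- detect_hotspots(img, label_mask(cytom, "cytosol", 250),
                         label_mask(phagm, "phagosome", 250), k_sd = 2)
  expect_equal(nrow(hs1$hotspots), 1)
  expect_equal(hs1$hotspots$phagosome_id, 1L)
  expect_lte(hs1$hotspots$border_dist_nm, 750)
  # F/F_ave map normalises by the cytosolic mean
  expect_equal(mean(hs1$f_over_fave[cytom > 0L]), 1, tolerance = 1e-9)

  expect_error(detect_hotspots(img, label_mask(matrix(0L, 40, 40), "cytosol", 250),
                               label_mask(phagm, "phagosome", 250)), "empty")
})

test_that("hotspot counts are monotone in k_sd and max_dist", {
  g <- gen_fluo8_frame(preset("hotspot", "shCTR", seed = 15), 30)
  n_k <- vapply(c(1, 2, 3, 4), function(k)
    nrow(detect_hotspots(g$image, g$cyto_mask, g$phag_mask, k_sd = k)$hotspots), 0)
  expect_true(all(diff(n_k) <= 0))
  n_d <- vapply(c(250, 500, 750, 1250), function(d)
    nrow(detect_hotspots(g$image, g$cyto_mask, g$phag_mask,
                         max_dist_nm = d)$hotspots), 0)
  expect_true(all(diff(n_d) >= 0))
})

test_that("hotspot detection matches a brute-force oracle on random frames", {
  for (i in 1:20) {
    g <- gen_fluo8_frame(preset("hotspot", "shCTR", seed = 300L + i), 6)
    hs <- detect_hotspots(g$image, g$cyto_mask, g$phag_mask)
    # oracle: average frames, threshold, flood fill, centroid distance scan
    d <- dim(g$image)
    pl <- Reduce(`+`, lapply(seq_len(d[2]), function(ti)
      get_plane(g$image, frame = ti))) / d[2]
    cy <- g$cyto_mask$labels > 0L
    thr <- mean(pl[cy]) + 2 * sd(pl[cy])
    ff <- flood_fill_oracle(g$phag_mask$labels == 0L & pl > thr, 8L)
    phag_px <- which(g$phag_mask$labels > 0L, arr.ind = TRUE)
    n_ok <- 0L
    for (lab in seq_len(ff$n)) {
      px <- which(ff$labels == lab, arr.ind = TRUE)
      if (nrow(px) < 4) next
      ry <- round(mean(px[, 1])); rx <- round(mean(px[, 2]))
      dmin <- min(sqrt((phag_px[, 1] - ry)^2 + (phag_px[, 2] - rx)^2))
      if (dmin <= 3) n_ok <- n_ok + 1L
    }
    expect_equal(nrow(hs$hotspots), n_ok)
  }
})

test_that("equal-rate scenarios give indistinguishable hotspot frequencies", {
  fa <- gen_fluo8_frame(preset("hotspot", "shCTR", seed = 17), 150)
  fb <- gen_fluo8_frame(preset("hotspot", "shSec22b", seed = 18), 150)
  ca <- detect_hotspots(fa$image, fa$cyto_mask, fa$phag_mask)$per_phagosome
  cb <- detect_hotspots(fb$image, fb$cyto_mask, fb$phag_mask)$per_phagosome
  b <- bootstrap_pct_change(as.numeric(ca), as.numeric(cb), n_boot = 2000,
                            seed = 5)
  expect_true(b$ci[1] < 0 && b$ci[2] > 0)  # CI covers no change
})

test_that("phagocytic index is internalised targets per 100 cells", {
  phag <- label_mask(matrix(rep(c(0L, 1L:10L), length.out = 400), 20, 20),
                     "phagosome", 250)
  cell <- label_mask(matrix(rep(1L:5L, each = 80), 20, 20), "cell", 250)
  expect_equal(phagocytic_index(phag, cell), 200)
  none <- label_mask(matrix(0L, 20, 20), "phagosome", 250)
  expect_equal(phagocytic_index(none, cell), 0)
  expect_error(phagocytic_index(phag, none), "no cells")
})
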