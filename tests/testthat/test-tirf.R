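# TIRF puncta detection, baseline exclusion, Boltzmann kinetics

test_that("detect_tirf_puncta applies the mean + 1 SD threshold and strict area rule", {
  cellm <- label_mask(matrix(1L, 64, 64), "cell", 110)
  # uniform cell: SD 0, strict > mean finds nothing
  uni <- image_stack(matrix(10, 64, 64), pixel_size_nm = 110)
  expect_equal(sum(detect_tirf_puncta(uni, cellm)$counts), 0L)

  # one 3x3 bright square -> 1 punctum of area 9
  pl <- matrix(10, 64, 64); pl[30:32, 30:32] <- 110
  ps <- detect_tirf_puncta(image_stack(pl, pixel_size_nm = 110), cellm)
  expect_equal(sum(ps$counts), 1L)
  expect_equal(ps$puncta$area_px, 9L)

  # a 2x2 square (area 4) fails the strict >4 px rule
  pl2 <- matrix(10, 64, 64); pl2[30:31, 30:31] <- 110
  # add a clear punctum elsewhere so the threshold is still meaningful
  pl2[10:12, 10:12] <- 110
  ps2 <- detect_tirf_puncta(image_stack(pl2, pixel_size_nm = 110), cellm)
  expect_equal(sum(ps2$counts), 1L)

  expect_error(detect_tirf_puncta(uni, label_mask(matrix(0L, 64, 64), "cell", 110)),
               "empty")
})

test_that("detection equals the brute-force oracle on random frames", {
  set.seed(101)
  cellm <- label_mask(matrix(1L, 48, 48), "cell", 110)
  for (i in 1:20) {
    pl <- matrix(rnorm(48 * 48, 20, 1), 48, 48)
    for (k in seq_len(sample(0:6, 1)))
      pl <- pl + 30 * exp(-(outer((seq_len(48) - runif(1, 8, 40))^2, rep(1, 48)) +
                            outer(rep(1, 48), (seq_len(48) - runif(1, 8, 40))^2)) / 8)
    img <- image_stack(pmax(pl, 0), pixel_size_nm = 110)
    got <- detect_tirf_puncta(img, cellm)
    thr <- mean(pl) + sd(pl)
    ora <- puncta_oracle(get_plane(img), matrix(TRUE, 48, 48), thr,
                         min_area = 4, keep_rule = "gt")
    expect_equal(unname(sum(got$counts)), ora$count)
    if (ora$count) expect_equal(sort(got$puncta$area_px), sort(ora$areas))
  }
})

test_that("puncta_timeseries tracks static movies and baseline exclusion works", {
  cellm <- label_mask(matrix(1L, 32, 32), "cell", 110)
  pl <- matrix(10, 32, 32); pl[10:12, 10:12] <- 60
  arr <- array(0, c(1, 4, 1, 32, 32))
  for (ti in 1:4) arr[1, ti, 1, , ] <- pl
  ts <- puncta_timeseries(image_stack(arr, pixel_size_nm = 110,
                                      frame_interval_s = 1), cellm)
  expect_true(all(ts$n == 1L))           # constant track
  expect_equal(ts$t_s, 0:3)

  # cells with baseline puncta are excluded; clean cohorts unchanged
  g_pre <- gen_tirf_series(preset("tirf", "KDEL", seed = 5), n_cells = 6,
                           duration_s = 40, dt_s = 10, pre_puncta_frac = 1)
  ts_pre <- exclude_baseline_cells(puncta_timeseries(g_pre$stack, g_pre$cell_mask))
  expect_length(ts_pre$cell_ids, 0)
  g_cl <- gen_tirf_series(preset("tirf", "KDEL", seed = 5), n_cells = 6,
                          duration_s = 40, dt_s = 10, pre_puncta_frac = 0)
  ts_cl <- exclude_baseline_cells(puncta_timeseries(g_cl$stack, g_cl$cell_mask))
  expect_length(ts_cl$cell_ids, 6)
})

test_that("fit_boltzmann recovers exact curves and flags degenerate input", {
  t <- seq(0, 420, by = 1)
  y <- 0 + (10 - 0) / (1 + exp((180 - t) / 30))
  fit <- fit_boltzmann(t, y)
  expect_true(fit$converged)
  expect_equal(fit$A1, 0, tolerance = 1e-4)
  expect_equal(fit$A2, 10, tolerance = 1e-4)
  expect_equal(fit$t50_s, 180, tolerance = 180 * 1e-4)
  expect_equal(fit$slope_s, 30, tolerance = 30 * 1e-4)
  expect_equal(predict(fit, 180), 5, tolerance = 1e-3)

  flat <- fit_boltzmann(t, rep(3, length(t)))
  expect_true(flat$degenerate)
  expect_equal(flat$A1, flat$A2)
  expect_error(fit_boltzmann(1:3, 1:3), "at least 6")
})

test_that("fit parameters transform correctly under time shift and scaling", {
  t <- seq(0, 420, by = 2)
  y <- 2 + 8 / (1 + exp((150 - t) / 25))
  f0 <- fit_boltzmann(t, y)
  fs <- fit_boltzmann(t + 100, y)        # time translation
  expect_equal(fs$t50_s, f0$t50_s + 100, tolerance = 1e-3)
  expect_equal(fs$slope_s, f0$slope_s, tolerance = 1e-3)
  fg <- fit_boltzmann(t, 3 * y)          # linear intensity scaling
  expect_equal(fg$A1, 3 * f0$A1, tolerance = 1e-3)
  expect_equal(fg$A2, 3 * f0$A2, tolerance = 1e-3)
  expect_equal(fg$slope_s, f0$slope_s, tolerance = 1e-3)
  # stimulus-relative reporting
  fr <- fit_boltzmann(t, y, stimulus_time_s = 50)
  expect_equal(fr$t50_s, f0$t50_s - 50, tolerance = 1e-3)
})

test_that("noisy-curve recovery: median relative error of slope and t50 < 10% at SNR 10", {
  set.seed(111)
  t <- seq(0, 420, by = 2)
  errs <- t(vapply(1:100, function(i) {
    y <- 10 / (1 + exp((180 - t) / 30)) + rnorm(length(t), 0, 1)  # SNR 10
    f <- fit_boltzmann(t, y)
    c(abs(f$t50_s - 180) / 180, abs(f$slope_s - 30) / 30)
  }, c(0, 0)))
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
})

test_that("rendered TIRF series reproduce the configured kinetics contrast", {
  fits <- lapply(c("KDEL", "Sec22b-OE"), function(cond) {
    g <- gen_tirf_series(preset("tirf", cond, seed = 8), n_cells = 3,
                         duration_s = 400, dt_s = 4)
    ts <- puncta_timeseries(g$stack, g$cell_mask)
    list(fit = fit_boltzmann(ts$t_s, rowMeans(ts$n)),
         area6 = mean(ts$mean_area_px[which.min(abs(ts$t_s - 360)), ],
                      na.rm = TRUE),
         cfg = preset("tirf", cond))
  })
  for (f in fits) {
    expect_true(f$fit$converged)
    expect_equal(f$fit$t50_s, f$cfg$tirf_t50_s, tolerance = 0.05)
    expect_equal(f$fit$slope_s, f$cfg$tirf_slope_s, tolerance = 0.1)
  }
  # accelerated recruitment: smaller slope parameter, and larger puncta
  expect_lt(fits[[2]]$fit$slope_s, fits[[1]]$fit$slope_s)
  expect_gt(fits[[2]]$area6, fits[[1]]$area6)
})
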