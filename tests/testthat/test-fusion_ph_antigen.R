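# FRET fusion index, pH calibration/inversion, antigen remaining

plf_fixture <- function(fret_val = 10, green_val = 5, red_total = 100) {
  # single cell 10x10, one phagosome of 20 px (5x4 block), uniform channels
  phagm <- matrix(0L, 10, 10); phagm[3:7, 3:6] <- 1L
  cellm <- matrix(1L, 10, 10)
  mk <- function(v) image_stack(matrix(v, 10, 10), pixel_size_nm = 110)
  fret <- mk(0); fret$data[1, 1, 1, , ][phagm == 1L] <- fret_val
  green <- mk(0); green$data[1, 1, 1, , ][phagm == 1L] <- green_val
  red <- mk(red_total / 100)  # 100 px cell -> total = red_total
  list(fret = fret, green = green, red = red,
       phag = label_mask(phagm, "phagosome", 110),
       cell = label_mask(cellm, "cell", 110))
}

test_that("plf_index matches the hand-computed arithmetic oracle exactly", {
  fx <- plf_fixture(fret_val = 10, green_val = 5, red_total = 100)
  m <- plf_index(fx$fret, fx$green, fx$red, fx$phag, fx$cell)
  expect_equal(m$plf_index, (10 / 5) / 100)         # mean ratio 2 over red 100
  expect_equal(m$fret_ratio, 10 * 20 / 100)         # FRET sum over red
  expect_equal(m$phagosome_count, 1L)

  z <- plf_fixture(fret_val = 0)
  expect_equal(plf_index(z$fret, z$green, z$red, z$phag, z$cell)$plf_index, 0)
})

test_that("plf_index scaling behaviour: joint FRET+red invariance, inverse green gain", {
  fx <- plf_fixture()
  base <- plf_index(fx$fret, fx$green, fx$red, fx$phag, fx$cell)$plf_index
  s <- 3.7
  fx2 <- fx; fx2$fret$data <- fx$fret$data * s; fx2$red$data <- fx$red$data * s
  expect_equal(plf_index(fx2$fret, fx2$green, fx2$red, fx$phag, fx$cell)$plf_index,
               base)
  fx3 <- fx; fx3$green$data <- fx$green$data * s
  expect_equal(plf_index(fx$fret, fx3$green, fx$red, fx$phag, fx$cell)$plf_index,
               base / s)
})

test_that("cells without phagosomes are flagged undefined, not zero", {
  phagm <- matrix(0L, 10, 20); phagm[3:7, 3:6] <- 1L
  cellm <- matrix(1L, 10, 20); cellm[, 11:20] <- 2L
  mk <- function(v) image_stack(matrix(v, 10, 20), pixel_size_nm = 110)
  fret <- mk(1); green <- mk(2); red <- mk(1)
  m <- plf_index(fret, green, red, label_mask(phagm, "phagosome", 110),
                 label_mask(cellm, "cell", 110))
  expect_true(is.na(m$plf_index[m$cell_id == 2]))
  expect_true(m$flagged[m$cell_id == 2])
  expect_false(is.na(m$plf_index[m$cell_id == 1]))
})

test_that("generated fusion stacks recover per-cell truth and the knockdown fold", {
  means <- vapply(c("shCTR", "shSec22b"), function(cond) {
    g <- gen_plf_stacks(preset("plf", cond, seed = 4), 25)
    m <- plf_index(g$fret, g$green, g$red, g$phag_mask, g$cell_mask)
    expect_equal(m$plf_index, g$truth$plf_true, tolerance = 0.02)
    mean(m$plf_index)
  }, 0)
  expect_equal(unname(means[2] / means[1]), 1.5, tolerance = 0.1)
})

test_that("pH calibration recovers a known Boltzmann and rejects bad input", {
  mkpair <- function(r) list(ex440 = image_stack(matrix(100 * r, 8, 8), 160),
                             ex480 = image_stack(matrix(100, 8, 8), 160))
  ph <- c(4, 5, 6, 7, 8, 9)
  truth <- function(p) 0.3 + (2.5 - 0.3) / (1 + exp((p - 6.3) / 0.5))
  cal <- fit_ph_calibration(lapply(ph, function(p) mkpair(truth(p))), ph)
  expect_equal(coef(cal)[["top"]], 2.5, tolerance = 1e-3)
  expect_equal(coef(cal)[["bottom"]], 0.3, tolerance = 1e-3)
  expect_equal(coef(cal)[["ph50"]], 6.3, tolerance = 1e-3)
  expect_equal(coef(cal)[["slope"]], 0.5, tolerance = 1e-3)
  expect_equal(cal$fit$direction, "descending")

  expect_error(fit_ph_calibration(lapply(c(4, 5), function(p) mkpair(truth(p))),
                                  c(4, 5)), ">= 4 distinct")
  expect_error(fit_ph_calibration(lapply(ph, function(p) mkpair(1)), ph),
               "constant")
  wob <- c(2.5, 0.6, 2.0, 0.5, 0.4, 0.3)  # large reversal
  expect_error(fit_ph_calibration(lapply(seq_along(ph),
                                         function(i) mkpair(wob[i])), ph),
               "non-monotone")
})

test_that("ratio -> pH inversion round-trips and respects monotonicity", {
  g <- gen_ph_images(preset("ph", "shCTR", seed = 9))
  cal <- fit_ph_calibration(g$calibration, g$buffer_ph)
  # round-trip at interior buffer points within 0.1 pH
  for (p in seq(5, 8, by = 0.5))
    expect_equal(ratio_to_ph(predict(cal, p), cal), p, tolerance = 0.1 / p)
  expect_lt(cal$roundtrip_max_err, 0.1)
  # larger ratio -> more acidic (descending curve)
  expect_lt(ratio_to_ph(2.0, cal), ratio_to_ph(0.8, cal))
  expect_warning(ratio_to_ph(10, cal), "clamped")
})

test_that("phagosomal pH is recovered from generated test images within 0.15", {
  cfg <- preset("ph", "shCTR", seed = 23)
  cfg$ph_true <- 6.0
  g <- gen_ph_images(cfg)
  cal <- fit_ph_calibration(g$calibration, g$buffer_ph)
  res <- phagosome_ph(g$test$ex440, g$test$ex480, g$test$phag_mask, cal)
  expect_equal(mean(res$ph), 6.0, tolerance = 0.15 / 6)
})

test_that("antigen remaining: arithmetic, invariance, errors", {
  g <- gen_antigen_image(preset("antigen", "siCTR", seed = 6), 20, 8)
  # ingested == free -> 100%
  same <- antigen_remaining(g$image, g$free_rois, g$free_rois)
  expect_equal(same$percent_remaining, rep(100, nrow(g$free_rois)),
               tolerance = 0.02)
  # explicit 50 vs 100 construction
  pl <- matrix(0, 40, 80)
  pl[11:20, 11:20] <- 50; pl[11:20, 51:60] <- 100
  img <- image_stack(pl, pixel_size_nm = 160)
  ing <- data.frame(cx = 15.5, cy = 15.5, r = 4)
  fre <- data.frame(cx = 55.5, cy = 15.5, r = 4)
  expect_equal(antigen_remaining(img, ing, fre)$percent_remaining, 50)
  # invariant under global illumination scaling
  img2 <- img; img2$data <- img$data * 11
  expect_equal(antigen_remaining(img2, ing, fre)$percent_remaining, 50)
  expect_error(antigen_remaining(img, ing, fre[0, ]), "at least one")
  dark <- image_stack(matrix(0, 40, 80), pixel_size_nm = 160)
  expect_error(antigen_remaining(dark, ing, fre), "zero free-bead")
})

test_that("knockdown scenario shows exacerbated antigen degradation", {
  pct <- vapply(c("siCTR", "siSec22b"), function(cond) {
    g <- gen_antigen_image(preset("antigen", cond, seed = 6), 40, 10)
    mean(antigen_remaining(g$image, g$ingested_rois, g$free_rois)$percent_remaining)
  }, 0)
  expect_lt(pct["siSec22b"], pct["siCTR"])
  expect_equal(unname(pct["siCTR"]), 70, tolerance = 0.1)
  expect_equal(unname(pct["siSec22b"]), 50, tolerance = 0.1)
})
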