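# data model, file round-trips, projections, background subtraction,
# connected components

test_that("ImageStack construction normalises shapes and validates metadata", {
  img <- image_stack(matrix(0, 8, 6), pixel_size_nm = 50)
  expect_equal(dim(img), c(1L, 1L, 1L, 8L, 6L))
  img3 <- image_stack(array(1, c(3, 4, 5)), pixel_size_nm = 50)
  expect_equal(dim(img3)[2], 3L)  # 3-D input maps to the time axis
  expect_error(image_stack(matrix(NA_real_, 2, 2), 50), "finite")
  expect_error(image_stack(matrix(0, 2, 2), -1), "positive")
})

test_that("TIFF write/read round-trips data and physical metadata", {
  set.seed(11)
  img <- image_stack(array(runif(3 * 16 * 16) * 1000, c(1, 3, 1, 16, 16)),
                     pixel_size_nm = 250, frame_interval_s = 3,
                     z_step_nm = 500)
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(img, f, bits = 64)
  back <- read_stack(f)
  expect_identical(back$data, img$data)       # lossless at 64-bit float
  expect_equal(back$pixel_size_nm, 250)       # stored pitch parsed back
  expect_equal(back$frame_interval_s, 3)

  # 16-bit integer storage is bit-identical for integral grids
  imi <- image_stack(matrix(sample(0:65535, 64), 8, 8), pixel_size_nm = 50)
  fi <- withr::local_tempfile(fileext = ".tif")
  write_stack(imi, fi, bits = 16)
  expect_identical(read_stack(fi)$data, imi$data)

  # 32-bit float storage is within single precision
  f32 <- withr::local_tempfile(fileext = ".tif")
  write_stack(img, f32, bits = 32)
  expect_equal(read_stack(f32)$data, img$data, tolerance = 1e-6)

  # override wins over stored metadata; 3-page file maps to t axis
  expect_equal(read_stack(f, pixel_size_nm = 50)$pixel_size_nm, 50)
  expect_equal(dim(read_stack(f))[2], 3L)
})

test_that("raw grid format round-trips and unreadable files error", {
  img <- image_stack(matrix(rnorm(36), 6, 6), pixel_size_nm = 110)
  f <- withr::local_tempfile(fileext = ".txt")
  write_grid(img, f)
  expect_equal(read_stack(f)$data, img$data, tolerance = 1e-15)
  bad <- withr::local_tempfile()
  writeLines("not an image", bad)
  expect_error(read_stack(bad), "unreadable")
  expect_error(read_stack(tempfile()), "not found")
})

test_that("LabelMask TIFF round-trip is exact", {
  m <- matrix(0L, 12, 12); m[3:5, 3:5] <- 2L; m[8:9, 8:10] <- 7L
  f <- withr::local_tempfile(fileext = ".tif")
  write_mask(label_mask(m, "phagosome", 50), f)
  back <- read_mask(f, "phagosome")
  expect_identical(back$labels, m)
  expect_equal(back$label_ids, c(2L, 7L))
})

test_that("background subtraction: percentile, region, clamping, idempotence", {
  img <- image_stack(matrix(10, 8, 8), pixel_size_nm = 50)
  expect_true(all(background_subtract(img, "percentile", 1)$data == 0))

  pl <- matrix(10, 10, 10); pl[4:6, 4:6] <- 100
  img2 <- image_stack(pl, pixel_size_nm = 50)
  bg <- matrix(1L, 10, 10); bg[4:6, 4:6] <- 0L
  out <- get_plane(background_subtract(img2, "region",
                                       label_mask(bg, "cytosol", 50)))
  expect_equal(out[5, 5], 90)
  expect_equal(out[1, 1], 0)
  # idempotent once the region mean is 0
  again <- background_subtract(image_stack(out, 50), "region",
                               label_mask(bg, "cytosol", 50))
  expect_equal(get_plane(again), out)
  expect_error(background_subtract(img2, "region",
                                   label_mask(matrix(0L, 10, 10), "cytosol", 50)),
               "empty")
  expect_error(background_subtract(img2, "percentile", 101), "percentile")
})

test_that("z projection matches brute-force reducers and preserves metadata", {
  img1 <- image_stack(matrix(3, 4, 4), pixel_size_nm = 50)
  expect_identical(project(img1, "max")$data, img1$data)

  arr <- array(0, c(1, 1, 3, 2, 2))
  arr[1, 1, 1, , ] <- 1; arr[1, 1, 2, , ] <- 2; arr[1, 1, 3, , ] <- 3
  imgz <- image_stack(arr, pixel_size_nm = 50)
  expect_true(all(get_plane(project(imgz, "sum")) == 6))

  set.seed(21)
  arr5 <- array(runif(2 * 5 * 6 * 6), c(1, 2, 5, 6, 6))
  img5 <- image_stack(arr5, pixel_size_nm = 50, frame_interval_s = 2)
  pm <- project(img5, "max")
  # loop oracle
  for (ti in 1:2) {
    ora <- matrix(-Inf, 6, 6)
    for (z in 1:5) ora <- pmax(ora, arr5[1, ti, z, , ])
    expect_equal(pm$data[1, ti, 1, , ], ora)
    for (z in 1:5)  # max projection dominates every plane
      expect_true(all(pm$data[1, ti, 1, , ] >= arr5[1, ti, z, , ]))
  }
  ps <- project(img5, "sum")
  expect_equal(ps$data[1, 1, 1, , ], apply(arr5[1, 1, , , ], c(2, 3), sum))
  expect_equal(pm$frame_interval_s, 2)
})

test_that("label_regions matches an independent flood-fill oracle", {
  expect_length(label_regions(matrix(FALSE, 5, 5))$label_ids, 0)
  m <- matrix(FALSE, 3, 3); m[1, 1] <- m[2, 2] <- TRUE
  expect_length(label_regions(m, 4)$label_ids, 2)
  expect_length(label_regions(m, 8)$label_ids, 1)

  set.seed(31)
  for (i in 1:100) {
    g <- matrix(runif(32 * 32) < 0.35, 32, 32)
    conn <- if (i %% 2) 4L else 8L
    got <- label_regions(g, conn)
    ora <- flood_fill_oracle(g, conn)
    expect_equal(length(got$label_ids), ora$n)
    # identical partitions: labels agree up to naming, and the raster
    # anchor order makes the naming identical too
    expect_identical(got$labels, ora$labels)
  }
})

test_that("SummaryTable round-trips losslessly through CSV", {
  tab <- summary_table(scenario = c("a", "b"), cell_id = c(1L, NA),
                       phagosome_id = c(2L, 3L), metric = c("m1", "m2"),
                       value = c(1.25, -0.5), units = c("nm", ""))
  f <- withr::local_tempfile(fileext = ".csv")
  write_summary_table(tab, f)
  expect_equal(read_summary_table(f), tab)
})

test_that("scenario configs validate, round-trip through JSON, and expose presets", {
  cfg <- scenario_preset("em", "shCTR")
  expect_equal(cfg$contact_rate, 4.5)
  expect_equal(scenario_preset("em", "shSec22b")$contact_rate, 3.0)
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario(cfg, f)
  expect_equal(read_scenario(f), cfg)
  expect_error(scenario_config("x", contact_rate = -1), "contact_rate")
  expect_error(scenario_config("x", large_contact_fraction = 2), "0, 1")
  expect_error(scenario_preset("em", "nope"), "unknown condition")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name":"x","bogus_field":1}', bad)
  expect_error(read_scenario(bad), "unknown scenario fields")
})
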