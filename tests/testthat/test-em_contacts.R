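# EM contact-site detection, filtering, statistics, F-test

circle_profile <- function(R = 1000, segs = list(), id = 1L) {
  em_profile(list(type = "circle", center = c(0, 0), radius_nm = R),
             er_segments = segs, phagosome_diameter_nm = 2 * R,
             phagosome_id = id)
}

# arc polyline at constant radial gap from a circle of radius R, with a
# given arc length measured along the polyline's own radius
arc_at_gap <- function(R, gap, arc_len, center_angle = 0, step = 2) {
  r <- R + gap
  theta <- arc_len / r
  ang <- seq(center_angle - theta / 2, center_angle + theta / 2,
             length.out = max(2, ceiling(arc_len / step) + 1))
  cbind(r * cos(ang), r * sin(ang))
}

test_that("detect_contacts handles empty, constant-gap and dipping arcs", {
  expect_equal(nrow(detect_contacts(circle_profile())$contacts), 0)

  # constant 25 nm gap over 100 nm -> one contact of length ~100
  p1 <- circle_profile(1000, list(arc_at_gap(1000, 25, 100)))
  cs <- detect_contacts(p1, gap_max_nm = 30, min_run_nm = 10)
  expect_equal(nrow(cs$contacts), 1)
  expect_equal(cs$contacts$arc_length_nm, 100, tolerance = 0.02)
  expect_lt(cs$contacts$min_gap_nm, 30)

  # radial gap dips within 30 nm twice, separated by an excursion to 80 nm
  s <- seq(0, 300, by = 1)
  gap_fun <- ifelse(s <= 100, 20, ifelse(s <= 200, 80, 20))
  ang <- s / 1000
  poly <- cbind((1000 + gap_fun) * cos(ang), (1000 + gap_fun) * sin(ang))
  cs2 <- detect_contacts(circle_profile(1000, list(poly)), min_run_nm = 20)
  expect_equal(nrow(cs2$contacts), 2)

  # degenerate zero-length polyline warns and is skipped
  degen <- rbind(c(1010, 0), c(1010, 0))
  expect_warning(out <- detect_contacts(circle_profile(1000, list(degen))),
                 "degenerate")
  expect_equal(nrow(out$contacts), 0)
})

test_that("filter_profiles applies the strict >1 um diameter rule", {
  ps <- lapply(c(400, 500, 600), circle_profile)  # diameters 0.8, 1.0, 1.2 um
  kept <- filter_profiles(ps)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$phagosome_diameter_nm, 1200)
  expect_length(filter_profiles(list()), 0)
})

test_that("contact_stats reproduces hand-computed summaries and flags empties", {
  lens <- list(c(90, 100, 80, 95), c(93, 85, 100, 90, 96))
  sets <- lapply(1:2, function(i) {
    structure(list(contacts = data.frame(segment_id = seq_along(lens[[i]]),
                                         arc_length_nm = lens[[i]],
                                         min_gap_nm = 20),
                   phagosome_id = i), class = "ContactSet")
  })
  st <- contact_stats(sets)
  expect_equal(st$mean_count, 4.5)
  expect_equal(st$median_length, 93)
  expect_equal(st$frac_large, 0)
  expect_s3_class(st$table, "SummaryTable")

  empty <- structure(list(contacts = data.frame(segment_id = integer(0),
                                                arc_length_nm = numeric(0),
                                                min_gap_nm = numeric(0)),
                          phagosome_id = 1L), class = "ContactSet")
  st0 <- contact_stats(list(empty))
  expect_equal(st0$mean_count, 0)
  expect_true(is.na(st0$median_length))
})

test_that("detect_contacts agrees with the 1 nm sampling oracle on random profiles", {
  set.seed(41)
  total_prev <- NULL
  for (i in 1:50) {
    g <- gen_em_profiles(scenario_config("x", seed = 1000L + i,
                                         contact_rate = 4,
                                         contact_length_median_nm = 90,
                                         contact_length_sigma = 0.5,
                                         large_contact_fraction = 0.05), 1)
    p <- g$profiles[[1]]
    got <- detect_contacts(p)
    ora <- contact_oracle(p)
    expect_equal(nrow(got$contacts), ora$count)
    if (ora$count > 0)
      expect_equal(sort(got$contacts$arc_length_nm), sort(ora$lengths),
                   tolerance = 2 / 90)  # within 2 nm
  }
})

test_that("total contact length is monotone in the gap threshold", {
  g <- gen_em_profiles(scenario_config("x", seed = 77L, contact_rate = 5), 10)
  for (p in g$profiles) {
    tot <- vapply(c(10, 20, 30, 45, 60),
                  function(gm) sum(detect_contacts(p, gap_max_nm = gm)$contacts$arc_length_nm),
                  0)
    expect_true(all(diff(tot) >= -1e-9))
  }
})

test_that("variance F-test matches the reference F distribution and var.test", {
  x <- c(1, 2, 3, 4, 5)
  same <- variance_f_test(x, x)
  expect_equal(same$F, 1)
  expect_equal(same$p, 1)

  set.seed(51)
  a <- rnorm(30, sd = 2); b <- rnorm(30, sd = 1)
  ft <- variance_f_test(a, b)
  expect_equal(ft$F, max(var(a), var(b)) / min(var(a), var(b)))
  expect_equal(ft$p, min(1, 2 * pf(ft$F, ft$df[1], ft$df[2], lower.tail = FALSE)))
  # independent cross-check against stats::var.test
  vt <- var.test(if (var(a) >= var(b)) a else b,
                 if (var(a) >= var(b)) b else a)
  expect_equal(ft$p, vt$p.value, tolerance = 1e-9)

  expect_error(variance_f_test(1, x), "at least 2")
  expect_error(variance_f_test(c(1, 1), x), "zero variance")
})

test_that("length-diversity F-test detects the knockdown contrast reliably", {
  # sample sizes as in the published comparison (172 vs 145 contacts); the
  # knockdown arm mixes in 3% very large contacts
  draw <- function(n, median, big_frac) {
    l <- rlnorm(n, log(median), 0.4)
    big <- runif(n) < big_frac
    l[big] <- runif(sum(big), 400, 600)
    l
  }
  set.seed(61)
  hits <- sum(vapply(1:100, function(i) {
    variance_f_test(draw(172, 93, 0), draw(145, 81, 0.03))$p < 0.05
  }, TRUE))
  expect_gte(hits, 95)
})
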