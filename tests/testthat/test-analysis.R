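test_that("moving average reports physical window widths and preserves means", {
  sm7 <- moving_average(rep(1, 50), 7, spacing = 0.256)
  expect_equal(attr(sm7, "window_mm"), 1.792) # the 1.8 mm EPID window
  sm3 <- moving_average(rep(1, 50), 3, spacing = 0.256)
  expect_equal(attr(sm3, "window_mm"), 0.768) # the 0.77 mm window
  expect_equal(as.numeric(sm7), rep(1, 50)) # constant input unchanged
  expect_error(moving_average(1:10, 4), "odd")
  set.seed(1)
  v <- stats::rnorm(101)
  sm <- moving_average(v, 9)
  # interior is mean-preserving and commutes with profile reversal
  expect_equal(sm[50], mean(v[46:54]))
  expect_equal(rev(as.numeric(moving_average(rev(v), 9))), as.numeric(sm))
})

test_that("despike_pair removes single-column pixilation spikes", {
  x <- rep(100, 200)
  clean <- despike_pair(x, x)
  expect_equal(clean$value, rep(100, 200)) # plain average when clean
  a <- x
  a[80] <- 110 # +10% single-column spike in one acquisition
  out <- despike_pair(a, x)
  expect_equal(out$value[80], 100) # output falls back to the clean profile
  expect_equal(out$n_used[80], 1L)
  expect_equal(out$value[-80], rep(100, 199)) # no clean column altered
  b <- x
  b[80] <- 112
  both <- despike_pair(a, b)
  expect_true(is.na(both$value[80])) # spiked in both: marked missing
  # sub-threshold wobble is left alone
  c2 <- x
  c2[50] <- 102
  expect_equal(despike_pair(c2, x)$value[50], 101)
})

test_that("despiking clears every injected spike over random positions", {
  set.seed(11)
  for (rep_i in 1:20) {
    base <- 100 + stats::rnorm(300, sd = 0.2)
    idx <- sample(10:290, 5)
    spiked <- base
    spiked[idx] <- base[idx] * (1 + sample(c(-1, 1), 5, TRUE) * stats::runif(5, 0.05, 0.2))
    out <- despike_pair(spiked, base)
    expect_equal(out$value[idx], base[idx], tolerance = 1e-9)
  }
})

test_that("open-field normalization is pointwise with a masked floor", {
  x <- seq(-5, 5, by = 0.5)
  y <- seq(-2, 2, by = 0.5)
  open <- vmatqa:::new_fluence_image(
    matrix(50, length(y), length(x)), x, y
  )
  expect_equal(
    unique(as.vector(normalize_to_open(open, open)$values)), 100
  )
  test <- open
  test$values <- open$values * 1.02
  expect_equal(unique(as.vector(normalize_to_open(test, open)$values)), 102)
  # floor masking
  open2 <- open
  open2$values[1, 1] <- 0.1
  expect_true(is.na(normalize_to_open(test, open2)$values[1, 1]))
  other <- vmatqa:::new_fluence_image(matrix(1, 2, 2), 1:2, 1:2)
  expect_error(normalize_to_open(test, other), "different grids")
})

test_that("strip statistics echo a uniform field without distortion", {
  x <- seq(-13.9, 13.9, by = 0.2)
  y <- x
  img <- vmatqa:::new_fluence_image(matrix(95, length(y), length(x)), x, y)
  strips <- tibble::tibble(index = 1:3, x_start = c(-6, -3, 0), x_end = c(-3, 0, 3))
  det <- detector_model("diode_array", diode_spacing = 0.2)
  rep_raw <- strip_stats(img, strips, det, rescale = "none")
  expect_equal(rep_raw$mean, rep(95, 3))
  expect_equal(rep_raw$sd, rep(0, 3))
  rep_scaled <- strip_stats(img, strips, det)
  expect_equal(rep_scaled$mean, rep(100, 3))
})

test_that("dose-rate profile comparison sees scale changes and asymmetry", {
  x <- seq(-15, 15, by = 0.1)
  base <- ifelse(abs(x) < 12.5, 100, 0)
  profs <- list(
    max = tibble::tibble(x = x, value = base),
    half = tibble::tibble(x = x, value = base),
    scaled = tibble::tibble(x = x, value = base * 1.02)
  )
  cmp <- profile_dr_compare(profs, reference = "max")
  expect_equal(cmp$max_dev_pct[cmp$bin == "half"], 0)
  expect_equal(cmp$max_dev_pct[cmp$bin == "scaled"], 2)
  expect_equal(cmp$flatness_pct, rep(0, 3)) # flat tops
  tilt <- tibble::tibble(x = x, value = base * (1 + 0.001 * x))
  cmp2 <- profile_dr_compare(list(max = profs$max, tilt = tilt), "max")
  expect_gt(cmp2$symmetry_pct[2], 0)
})

test_that("simulated open fields read identically across dose-rate bins", {
  det <- detector_model("diode_array")
  profs <- lapply(c(1, 1 / 4, 1 / 32), function(f) {
    plan <- gen_utility_fields("open_field", mu = 50, dr_factor = f)
    img <- render_fluence(
      simulate_delivery(plan, errors = error_model(dr_switch_lag = 0), dt = 0.05),
      det
    )
    extract_profile(img, y_range = c(-0.5, 0.5))
  })
  names(profs) <- c("b0", "b2", "b5")
  cmp <- profile_dr_compare(profs, reference = "b0")
  expect_true(all(cmp$max_dev_pct < 0.1)) # ideal delivery is DR-independent
})

test_that("picket aggregation reproduces the printed summary arithmetic", {
  peaks <- reference_readings("picket_peaks")
  rep <- aggregate_pickets(peaks)
  # picket 4: static peaks 0.06, 0.14, 0.14, 0.06
  expect_equal(rep$static_average[4], 0.10)
  expect_equal(rep$static_range[4], 0.08)
  expect_equal(rep$arc_minus_average[4], 0.09)
  # picket 1: mean of -9.16, -9.06, -9.08, -9.16 before rounding
  expect_equal(rep$static_average[1], -9.115)
  expect_true(all(rep$static_range >= 0))
  # identical acquisitions collapse to zero range and deviation
  same <- tidyr::expand_grid(
    acquisition = c("a", "b", "arc1"), picket = 1:3
  )
  same$kind <- ifelse(same$acquisition == "arc1", "arc", "static")
  same$position <- same$picket * 1.0
  rep0 <- aggregate_pickets(same)
  expect_equal(rep0$static_range, rep(0, 3))
  expect_equal(rep0$arc_minus_average, rep(0, 3))
  expect_error(aggregate_pickets(peaks[peaks$kind == "arc", ]), "static")
})

test_that("tied picket maxima are flagged, not silently resolved", {
  x <- seq(-2, 2, by = 0.1)
  v <- rep(1, length(x))
  v[abs(x - 0) < 0.25] <- 5 # flat-topped picket: several equal maxima
  pk <- find_picket_peaks(tibble::tibble(x = x, value = v), 1)
  expect_true(pk$tie)
  expect_equal(pk$x_peak, -0.2) # broken toward smaller x
  expect_error(
    find_picket_peaks(tibble::tibble(x = x, value = v), 3),
    "expected 3"
  )
})

test_that("chamber report reproduces the stability and linearity ratios", {
  rep <- chamber_report(
    reference_readings("chamber_static"),
    reference_readings("chamber_arc"),
    reference_readings("dmlc_gravity")
  )
  a6 <- rep$arc_static[rep$arc_static$energy == "6 MV", ]
  expect_equal(a6$ratio_rounded[a6$mu == 36], 0.994)
  expect_equal(a6$ratio_rounded[a6$mu == 1000], 1.001)
  a10 <- rep$arc_static[rep$arc_static$energy == "10 MV", ]
  expect_equal(a10$ratio_rounded[a10$mu == 36], 0.994)
  expect_equal(a10$ratio_rounded[a10$mu == 1000], 0.999)
  expect_true(all(rep$linearity$deviation <= 0.003)) # within 0.3%
  expect_equal(rep$dmlc$ratio_rounded,
               c(1.001, 0.996, 1.001, 1.001, 0.996))
  # identical readings give unity everywhere
  st <- tibble::tibble(energy = "6 MV", mu = c(36, 1000), reading = c(1, 1000 / 36))
  ar <- tibble::tibble(energy = "6 MV", mu = c(36, 1000), sense = "CW",
                       reading = c(1, 1000 / 36))
  rep0 <- chamber_report(st, ar)
  expect_equal(rep0$arc_static$ratio, c(1, 1))
  expect_equal(rep0$linearity$deviation, 0)
  expect_error(
    chamber_report(st[st$mu == 36, ], ar),
    "missing static"
  )
})

test_that("imager centre report measures per-angle deviations from mean", {
  rep <- center_pixel_report(reference_readings("epid_centers"))
  expect_equal(rep$x_dev[rep$angle == 270], -0.015)
  expect_equal(mean(rep$y), 13.2675)
  expect_equal(rep$y_dev, c(0.1025, 0.0025, 0.0025, -0.1075))
  same <- tibble::tibble(angle = c(0, 90), x = c(1, 1), y = c(2, 2))
  expect_equal(center_pixel_report(same)$x_dev, c(0, 0))
})
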