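test_that("dose-rate bin table halves from the maximum and rounds half-up", {
  tbl <- build_bin_table(600, 6)
  expect_equal(tbl$nominal, c(600L, 300L, 150L, 75L, 38L, 19L))
  expect_equal(tbl$exact, 600 / 2^(0:5))
  expect_equal(build_bin_table(600, 1)$nominal, 600L)
  expect_equal(build_bin_table(480, 3)$exact, c(480, 240, 120))
  # exact_bins[k] * 2^k reconstructs dr_max exactly, for awkward maxima too
  for (drm in c(600, 435, 475, 123.4)) {
    tbl <- build_bin_table(drm, 6)
    expect_identical(tbl$exact * 2^tbl$bin, rep(drm, 6))
  }
  expect_error(build_bin_table(-1, 6), "positive")
  expect_error(build_bin_table(600, 0), ">= 1")
})

make_seg <- function(d_mu, mlc = 0, jaw = 0, theta = 0, dr_cap = NA_real_) {
  structure(
    list(d_mu = d_mu, d_theta = theta, max_leaf_travel = mlc,
         jaw_travel = jaw, dr_cap = dr_cap),
    class = "segment_kinematics"
  )
}

test_that("select_bin picks the highest dose rate every axis can follow", {
  lim <- machine_limits()
  # 10 cm in 50 MU at 10 MU/s is exactly 2 cm/s: top bin, on the edge
  expect_equal(select_bin(make_seg(50, mlc = 10), lim),
               list(bin = 0L, limiting_axis = "none", capped = FALSE))
  # one resolution step less forces a bin drop, leaves limiting
  s49 <- select_bin(make_seg(49, mlc = 10), lim)
  expect_equal(s49$bin, 1L)
  expect_equal(s49$limiting_axis, "mlc")
  # zero travel runs flat out
  expect_equal(select_bin(make_seg(100), lim)$bin, 0L)
  # prescribed cap forbids the upper bins
  expect_equal(select_bin(make_seg(100, dr_cap = 1 / 8), lim)$bin, 3L)
  # nothing feasible: lowest bin, flagged
  s <- select_bin(make_seg(0.5, mlc = 15), lim)
  expect_true(s$capped)
  expect_equal(s$bin, lim$n_dr_bins - 1L)
  # zero MU with travel is an instantaneous-motion segment
  expect_error(select_bin(make_seg(0, mlc = 1), lim), "instantaneous")
})

test_that("select_bin agrees with a brute-force scan over random segments", {
  lim <- machine_limits()
  bins <- build_bin_table(lim$dr_max, lim$n_dr_bins)
  brute <- function(seg) {
    caps <- if (is.na(seg$dr_cap)) 1 else seg$dr_cap
    allowed <- which(bins$exact <= caps * lim$dr_max * (1 + 1e-12)) - 1L
    for (k in allowed) {
      rate <- bins$exact[k + 1] / 60
      ok <- seg$max_leaf_travel * rate / seg$d_mu <= lim$mlc_speed_max * (1 + 1e-9) &&
        seg$jaw_travel * rate / seg$d_mu <= lim$jaw_speed_max * (1 + 1e-9) &&
        seg$d_theta * rate / seg$d_mu <= lim$gantry_speed_max * (1 + 1e-9)
      if (ok) return(k)
    }
    max(allowed)
  }
  set.seed(42)
  for (i in 1:1000) {
    seg <- make_seg(
      d_mu = stats::runif(1, 0.1, 300),
      mlc = stats::runif(1, 0, 20),
      jaw = stats::runif(1, 0, 20),
      theta = stats::runif(1, 0, 180),
      dr_cap = sample(c(NA, 1, 1 / 2, 1 / 8, 1 / 32), 1)
    )
    expect_equal(select_bin(seg, lim)$bin, brute(seg))
  }
})

test_that("max-speed inversion recovers the configured axis maxima", {
  expect_equal(invert_max_speed(50, 10, 600), 2.0)
  expect_equal(invert_max_speed(300, 180, 600), 6.0)
  expect_equal(invert_max_speed(200 / 3, 10, 600), 1.5)
  expect_error(invert_max_speed(0, 10, 600), "positive")
})

test_that("segment kinematics difference control points correctly", {
  cp0 <- control_point(0, gantry = 0, a = -5, b = -4.2)
  cp1 <- control_point(50, gantry = 180, a = 5, b = 5.8)
  seg <- segment_kinematics(cp0, cp1)
  expect_equal(seg$d_mu, 50)
  expect_equal(seg$d_theta, 180)
  expect_equal(seg$max_leaf_travel, 10)
  # identical control points give all-zero kinematics
  z <- segment_kinematics(cp0, cp0)
  expect_equal(z$d_mu, 0)
  expect_equal(z$max_leaf_travel, 0)
  expect_error(segment_kinematics(cp1, cp0), "decreases")
})

test_that("validate_plan flags gap, range and MU-per-degree violations", {
  lim <- machine_limits()
  # a clean arc segment at the between-strip dose rate: 2.5 MU over 12 deg
  # is 0.208 MU/deg, comfortably above the 0.1 floor
  ok <- vmat_plan("ok", dplyr::bind_rows(
    control_point(0, gantry = 0, a = -5, b = 5),
    control_point(2.5, gantry = 12, a = -5, b = 5)
  ))
  expect_equal(nrow(validate_plan(ok, lim)), 0L)
  expect_equal(2.5 / 12, 0.2083, tolerance = 1e-3)

  # 0.05 MU/deg sits below the floor
  low <- vmat_plan("low", dplyr::bind_rows(
    control_point(0, gantry = 0, a = -5, b = 5),
    control_point(0.6, gantry = 12, a = -5, b = 5)
  ))
  v <- validate_plan(low, lim)
  expect_equal(v$type, "mu_per_degree")
  expect_equal(v$value, 0.05)

  # a 3 mm opening violates the 5 mm minimum gap
  gap <- vmat_plan("gap", dplyr::bind_rows(
    control_point(0, a = -0.15, b = 0.15),
    control_point(10, a = -0.15, b = 0.15)
  ))
  expect_true(all(validate_plan(gap, lim)$type == "min_gap"))

  # out-of-range leaf
  rng <- vmat_plan("rng", dplyr::bind_rows(
    control_point(0, a = -5, b = 21),
    control_point(10, a = -5, b = 21)
  ))
  expect_true("leaf_range" %in% validate_plan(rng, lim)$type)

  # parked pairs are exempt from the gap check
  a <- rep(-19.5, 40)
  parked <- vmat_plan("parked", dplyr::bind_rows(
    control_point(0, a = a, b = a),
    control_point(10, a = a, b = a)
  ))
  expect_equal(nrow(validate_plan(parked, lim)), 0L)
})

test_that("MU quantization slack keeps floor-exact strips deliverable", {
  # a strip planned exactly at the floor whose MU rounds down by half a
  # resolution step must not be flagged
  lim <- machine_limits()
  p <- vmat_plan("edge", dplyr::bind_rows(
    control_point(0, gantry = 0, a = -5, b = 5),
    control_point(0.9, gantry = 9.375, a = -5, b = 5) # 0.9375 quantized
  ))
  expect_equal(nrow(validate_plan(p, lim)), 0L)
})
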