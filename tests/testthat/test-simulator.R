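test_that("segment durations follow the selected dose-rate bin", {
  tr50 <- simulate_delivery(gen_speed_limit_test("mlc", 10))
  expect_equal(max(tr50$samples$time), 5) # 50 MU at 10 MU/s
  expect_equal(tr50$events$bin, 0L)
  tr49 <- simulate_delivery(gen_speed_limit_test("mlc", 10, mu_override = 49))
  expect_equal(max(tr49$samples$time), 9.8) # dropped to half maximum
  expect_equal(tr49$events$bin, 1L)
  trs <- simulate_delivery(gen_utility_fields("static_mu", mu = 100))
  expect_equal(max(trs$samples$time), 10)
  expect_equal(max(apply(trs$bank_a, 2, function(c) diff(range(c)))), 0) # no motion
})

test_that("cumulative MU is conserved exactly for every generated plan", {
  plans <- list(
    gen_picket_fence(),
    gen_speed_limit_test("jaw"),
    gen_dr_gs_strip_test(), # includes deliberate over-maximum strips
    gen_mlc_speed_strip_test(),
    gen_reversal_test(speed_factors = 1)[[1]],
    gen_dr_change_test("increase")$test,
    gen_utility_fields("dmlc_gravity")
  )
  for (p in plans) {
    tr <- simulate_delivery(p)
    expect_identical(max(tr$samples$cum_mu), max(p$control_points$cum_mu))
    expect_true(all(diff(tr$samples$cum_mu) > -1e-12))
    expect_true(all(diff(tr$samples$time) > 0))
  }
})

test_that("per-sample leaf motion respects the speed limit", {
  tr <- simulate_delivery(gen_mlc_speed_strip_test())
  dt <- diff(tr$samples$time)
  max_step <- apply(abs(diff(tr$bank_a)), 1, max)
  expect_true(all(max_step <= machine_limits()$mlc_speed_max * dt + 1e-9))
})

test_that("over-maximum strips are delivered at a lower bin, dose intact", {
  # the 1.2x dose-rate strip cannot run at 12 MU/s: the controller keeps
  # the plan's MU and extends the dwell (gantry becomes the limiting axis
  # for the 1.2x gantry-speed strip)
  plan <- gen_dr_gs_strip_test()
  tr <- simulate_delivery(plan)
  ev <- tr$events
  dwell <- ev[ev$segment %% 2 == 0, ] # strip dwells alternate with moves
  expect_equal(max(tr$samples$cum_mu), max(plan$control_points$cum_mu))
  # planned dwell at 1.2x DR takes 20/12 s; delivered at bin 0 it takes 2 s
  seg7 <- ev[ev$segment == 14, ]
  expect_equal(seg7$bin, 0L)
  expect_equal(seg7$duration, 2)
})

test_that("sweep fluence matches the closed form and converges with dt", {
  # 1 cm gap at 0.74 cm/s and 10 MU/s: interior fluence = gap/speed * rate
  plan <- gen_utility_fields("dmlc_gravity")
  det <- detector_model("diode_array", blur_sigma = 0)
  expected <- 1 / 0.74 * 10
  err_at <- function(dt) {
    img <- render_fluence(simulate_delivery(plan, dt = dt), det)
    got <- img$values[which.min(abs(img$y)), which.min(abs(img$x - 0.5))]
    abs(got - expected) / expected
  }
  e_coarse <- err_at(0.05)
  e_default <- err_at(0.01)
  expect_lt(e_default, 0.005)
  expect_lte(e_default, e_coarse + 1e-6)
})

test_that("reversal over-travel inserts bounded triangular excursions", {
  p <- gen_reversal_test(speed_factors = 1)[[1]]
  delta <- 0.05
  tr0 <- simulate_delivery(p, errors = error_model(dr_switch_lag = 0))
  tr1 <- simulate_delivery(p, errors = error_model(
    reversal_overtravel = delta, dr_switch_lag = 0
  ))
  # every direction change reverses all 40 pairs on both banks
  expect_equal(sum(tr1$events$n_reversals), 80 * nrow(p$meta$turns))
  # the leaves overshoot the programmed extreme by exactly delta; compare
  # within the first zigzag excursion, before the sweep moves on
  t_cut <- tr1$events$time_start[3]
  m1 <- max(tr1$bank_b[tr1$samples$time <= t_cut, 20])
  m0 <- max(tr0$bank_b[tr0$samples$time <= t_cut, 20])
  expect_equal(m1 - m0, delta, tolerance = 1e-6)
  # and MU is still conserved
  expect_identical(max(tr1$samples$cum_mu), max(p$control_points$cum_mu))
})

test_that("systematic leaf offsets shift rendered pickets bodily", {
  plan <- gen_picket_fence(picket_positions = c(-3, 3))
  err <- error_model(leaf_offset = 0.08)
  img <- render_fluence(simulate_delivery(plan, errors = err),
                        detector_model("epid", extent = c(28, 4)))
  pk <- find_picket_peaks(img, 2)
  expect_equal(pk$x_peak, c(-3, 3) + 0.08, tolerance = 0.013)
})

test_that("render noise is seed-deterministic and off by default", {
  tr <- simulate_delivery(gen_utility_fields("open_field"), dt = 0.05)
  det <- detector_model("diode_array")
  a <- render_fluence(tr, det)
  b <- render_fluence(tr, det)
  expect_identical(a$values, b$values) # noiseless render is deterministic
  noisy <- error_model(noise_sigma = 0.02)
  n1 <- render_fluence(tr, det, errors = noisy, seed = 7)
  n2 <- render_fluence(tr, det, errors = noisy, seed = 7)
  n3 <- render_fluence(tr, det, errors = noisy, seed = 8)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  # pixilation lines scale single columns
  lines <- error_model(pixilation_lines = data.frame(column = 5, amplitude = 0.1))
  lined <- render_fluence(tr, det, errors = lines, seed = 1)
  expect_equal(lined$values[, 5], a$values[, 5] * 1.1)
  expect_equal(lined$values[, 6], a$values[, 6])
})
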