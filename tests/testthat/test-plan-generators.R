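lim <- machine_limits()

test_that("speed-limit tests compute the threshold MU for each axis", {
  expect_equal(glance(gen_speed_limit_test("mlc", 10))$total_mu, 50)
  expect_equal(glance(gen_speed_limit_test("gantry", 180))$total_mu, 300)
  expect_equal(glance(gen_speed_limit_test("jaw", 10))$total_mu, 66.7)
  p <- gen_speed_limit_test("mlc", 10, mu_override = 42)
  expect_equal(glance(p)$total_mu, 42)
  expect_equal(nrow(validate_plan(gen_speed_limit_test("jaw"), lim)), 0L)
})

test_that("picket fence programs pickets and localized errors", {
  plan <- gen_picket_fence()
  expect_equal(plan$meta$picket_positions, seq(-9, 9, 3))
  expect_equal(plan$meta$gap, 0.5)
  # error fence defaults to the wider 6 mm gap and alters only the named
  # pairs' trajectories
  ep <- gen_picket_fence(errors = list(
    list(pair = 20, widen_to = 0.15), list(pair = 25, shift = 0.05)
  ))
  expect_equal(ep$meta$gap, 0.6)
  cps <- ep$control_points
  base <- cps$a10
  expect_equal(cps$a11, base) # untouched pair matches the common sweep
  expect_false(isTRUE(all.equal(cps$a20, base)))
  expect_false(isTRUE(all.equal(cps$a25, base)))
  # rejections
  expect_error(gen_picket_fence(gap = 0.3), "minimum gap")
  expect_error(gen_picket_fence(picket_positions = c(0, 0.5)), "spacing")
  expect_error(gen_picket_fence(picket_width = 0.6), "smaller than the gap")
  # empty picket list degenerates to a plain sweep
  sweep <- gen_picket_fence(picket_positions = numeric(0))
  expect_equal(nrow(sweep$control_points), 2L)
})

test_that("picket fence gap narrows transiently by the strip width only", {
  # the localized 1 mm enhancement requires the leading leaf to pause at
  # the strip's far edge while the trailing leaf closes in: the only
  # deliverability findings on a 5 mm fence are those transient gap
  # reductions, and they are bounded by the picket width
  v <- validate_plan(gen_picket_fence(), lim)
  expect_true(all(v$type == "min_gap"))
  expect_true(all(v$value >= 0.5 - 0.1 - 1e-9))
})

test_that("DR:GS strips share arc span, dose and MU bookkeeping", {
  plan <- gen_dr_gs_strip_test()
  sp <- plan$strip_specs
  matched <- sp$dr_factor <= 1 & sp$gs_factor <= 1
  expect_equal(unique(sp$arc_span[matched]), 12) # Eq-driven common span
  expect_equal(sp$arc_span[sp$dr_factor > 1], 10)
  expect_equal(sp$arc_span[sp$gs_factor > 1], 14.4)
  # between-strip move: 3 cm at 1.5 cm/s and max/8 gives 2.5 MU
  expect_equal(plan$meta$move_mu, 2.5)
  # total MU = strips + moves exactly
  n_moves <- nrow(sp) + 1 # lead-in and lead-out included
  expect_equal(
    max(plan$control_points$cum_mu),
    sum(sp$planned_mu) + n_moves * plan$meta$move_mu
  )
  expect_equal(nrow(validate_plan(plan, lim)), 0L)
  # an over-long plan is rejected with the limiting sum reported
  expect_error(gen_dr_gs_strip_test(mu_strip = 70), "deg")
})

test_that("MLC-speed strips have constant dose and floor-set gantry speed", {
  plan <- gen_mlc_speed_strip_test()
  expect_equal(unique(plan$strip_specs$planned_mu), 15) # 3 * 10 / 2
  expect_equal(plan$meta$gantry_speed, 3.125) # (18.75/60) / 0.1
  expect_equal(nrow(validate_plan(plan, lim)), 0L)
  # the minimum gap performs poorly at maximum leaf speed and is refused
  expect_error(gen_mlc_speed_strip_test(gap = 0.5), "gap")
})

test_that("reversal plans record traversal counts and turn geometry", {
  plans <- gen_reversal_test(speed_factors = c(1, 0.18))
  p <- plans$v1.00
  expect_equal(p$strip_specs$traversal_count, c(1, 3, 3, 3, 9))
  expect_equal(plans$v0.18$meta$leaf_speed, 0.36) # the reference speed
  turns <- p$meta$turns
  expect_true(all(c(-5.6, -1.6, 3.6, 7.6, 10.6) %in% turns$position))
  expect_equal(sum(turns$position == 10.6), 4) # oscillation cycles
  expect_equal(nrow(validate_plan(p, lim)), 0L)
  # per-strip planned fluence is proportional to the recorded traversal
  # count (same speed and dose rate throughout)
  expect_equal(
    p$strip_specs$traversal_count / p$strip_specs$traversal_count[1],
    c(1, 3, 3, 3, 9)
  )
})

test_that("dose-rate change tests step the prescribed bins", {
  inc <- gen_dr_change_test("increase")
  expect_equal(inc$test$strip_specs$dr_factor * 32,
               c(1, 2, 4, 8, 16, 32, 1, 32))
  dec <- gen_dr_change_test("decrease")
  expect_equal(dec$test$strip_specs$dr_factor * 32,
               c(32, 16, 8, 4, 2, 1, 32, 1))
  expect_equal(inc$test$meta$gantry_speed, 3.125)
  expect_equal(inc$reference$meta$leaf_speed, 0.25)
  # reference differs from test only in sweep speed
  expect_equal(inc$reference$strip_specs$dr_factor, inc$test$strip_specs$dr_factor)
  expect_equal(nrow(validate_plan(inc$test, lim)), 0L)
  expect_equal(nrow(validate_plan(inc$reference, lim)), 0L)
})

test_that("utility fields reproduce the published geometry", {
  g <- gen_utility_fields("dmlc_gravity")
  expect_equal(g$meta$gantry_speed, 180 / (23 / 0.74)) # 5.79 deg/s
  expect_equal(round(g$meta$gantry_speed, 1), 5.8)
  s <- gen_utility_fields("static_mu")
  expect_equal(glance(s)$total_mu, 36)
  arc <- gen_utility_fields("arc_mu")
  expect_equal(glance(arc)$total_mu / 360, 2.78, tolerance = 1e-3)
  for (p in list(g, s, arc, gen_utility_fields("open_field"))) {
    expect_equal(nrow(validate_plan(p, lim)), 0L)
  }
})
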