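# memoized heavy fixtures shared across test files; everything is
# generated in code, noiseless unless a test injects errors explicitly
.fx <- new.env(parent = emptyenv())

fx <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

no_lag <- function() error_model(dr_switch_lag = 0)

# picket fences -------------------------------------------------------------
fence_image <- function(arc = 0) {
  fx(paste0("fence_", arc), {
    plan <- gen_picket_fence(arc = arc)
    img <- render_fluence(simulate_delivery(plan), detector_model("epid"))
    list(plan = plan, image = img)
  })
}

fence_error_case <- function(widen_pair = 20, shift_pair = 25) {
  key <- paste0("fence_err_", widen_pair, "_", shift_pair)
  fx(key, {
    plan <- gen_picket_fence(
      errors = list(
        list(pair = widen_pair, widen_to = 0.15),
        list(pair = shift_pair, shift = 0.05)
      ),
      arc = 356
    )
    img <- render_fluence(simulate_delivery(plan), detector_model("epid"))
    meas <- analyze_picket_image(img, plan)
    list(plan = plan, image = img, meas = meas,
         flags = detect_picket_errors(meas, plan))
  })
}

# strip tests ---------------------------------------------------------------
open_image <- function(detector) {
  fx(paste0("open_", detector$kind), {
    render_fluence(
      simulate_delivery(gen_utility_fields("open_field"), errors = no_lag()),
      detector
    )
  })
}

drgs_report <- function() {
  fx("drgs_report", {
    det <- detector_model("diode_array")
    plan <- gen_dr_gs_strip_test()
    img <- render_fluence(simulate_delivery(plan, errors = no_lag()), det)
    strip_stats(normalize_to_open(img, open_image(det)), plan$strip_specs, det)
  })
}

mlc_speed_report <- function() {
  fx("mlc_speed_report", {
    det <- detector_model("epid")
    plan <- gen_mlc_speed_strip_test()
    img <- render_fluence(simulate_delivery(plan, errors = no_lag()), det)
    strip_stats(normalize_to_open(img, open_image(det)), plan$strip_specs, det)
  })
}

# reversal test -------------------------------------------------------------
reversal_plans <- function() {
  fx("reversal_plans", gen_reversal_test(speed_factors = c(1, 0.18)))
}

reversal_det <- function() detector_model("epid", extent = c(26, 4))

reversal_reference_image <- function() {
  fx("reversal_ref_img", {
    render_fluence(
      simulate_delivery(reversal_plans()$v0.18, errors = no_lag()),
      reversal_det()
    )
  })
}

reversal_report_for <- function(delta) {
  fx(paste0("reversal_rep_", delta), {
    p <- reversal_plans()$v1.00
    err <- error_model(reversal_overtravel = delta, dr_switch_lag = 0)
    img <- render_fluence(simulate_delivery(p, errors = err), reversal_det())
    prof <- extract_profile(
      normalize_to_open(img, reversal_reference_image()),
      pair = 20
    )
    reversal_analysis(prof, p)
  })
}

# dose-rate change test -----------------------------------------------------
dr_change_profile <- function(lag = 0.25) {
  fx(paste0("drchg_prof_", lag), {
    pair <- gen_dr_change_test("increase")
    det <- detector_model("epid", extent = c(28, 4))
    err <- error_model(dr_switch_lag = lag)
    img_t <- render_fluence(simulate_delivery(pair$test, errors = err), det)
    img_r <- render_fluence(simulate_delivery(pair$reference, errors = err), det)
    list(
      pair = pair,
      profile = extract_profile(normalize_to_open(img_t, img_r), pair = 20)
    )
  })
}
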