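#' Injectable delivery-error model
#'
#' Collects the delivery imperfections the simulator can inject: a
#' systematic leaf position offset, leaf over-travel past programmed
#' direction reversals, the dose-rate bin switching lag, multiplicative
#' detector noise and vertical pixilation lines (applied at render time
#' only, under an explicit seed).
#'
#' @param leaf_offset Systematic leaf position offset, cm. A scalar applies
#'   to every leaf; a list `list(bank_a =, bank_b =)` of length-40 vectors
#'   applies per leaf.
#' @param reversal_overtravel Distance a leaf travels past a programmed
#'   reversal before returning, cm (>= 0). The leaf proceeds past the turn
#'   point at its incoming speed, then returns to the planned trajectory, a
#'   triangular excursion that locally increases open time near the
#'   junction.
#' @param dr_switch_lag Duration of a dose-rate bin transition, seconds:
#'   the delivered rate ramps linearly between bins over this window,
#'   centred on the control point. `NA` (default) uses the machine's
#'   `dr_switch_time`; 0 switches instantly.
#' @param noise_sigma Multiplicative Gaussian noise fraction on rendered
#'   fluence (0 = noiseless).
#' @param pixilation_lines Optional tibble/data.frame with columns `column`
#'   (pixel column index) and `amplitude` (fractional amplitude) of
#'   vertical detector pixilation artefacts.
#' @return An object of class `error_model`.
#' @export
error_model <- function(leaf_offset = 0, reversal_overtravel = 0,
                        dr_switch_lag = NA_real_, noise_sigma = 0,
                        pixilation_lines = NULL) {
  if (reversal_overtravel < 0) stop("over-travel must be >= 0", call. = FALSE)
  if (!is.na(dr_switch_lag) && dr_switch_lag < 0) {
    stop("dr_switch_lag must be >= 0", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(
    list(
      leaf_offset = leaf_offset,
      reversal_overtravel = reversal_overtravel,
      dr_switch_lag = dr_switch_lag,
      noise_sigma = noise_sigma,
      pixilation_lines = pixilation_lines
    ),
    class = "error_model"
  )
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "<error_model> offset %s cm, over-travel %g cm, lag %s s, noise %g\n",
    if (is.list(x$leaf_offset)) "per-leaf" else format(x$leaf_offset),
    x$reversal_overtravel,
    if (is.na(x$dr_switch_lag)) "machine" else format(x$dr_switch_lag),
    x$noise_sigma
  ))
  invisible(x)
}

offset_matrix <- function(leaf_offset, n, bank) {
  if (is.list(leaf_offset)) {
    off <- leaf_offset[[paste0("bank_", bank)]]
    if (is.null(off)) off <- 0
    matrix(rep_len(off, N_PAIRS), nrow = n, ncol = N_PAIRS, byrow = TRUE)
  } else {
    matrix(leaf_offset, nrow = n, ncol = N_PAIRS)
  }
}

#' Simulate delivery of a plan
#'
#' Time-stepped model of plan execution on a binned-dose-rate controller.
#' For each control-point segment the controller runs at the dose rate
#' selected by [select_bin()] (respecting any prescribed per-segment cap);
#' axes move at constant speed across the segment, extended in time when an
#' axis would otherwise exceed its maximum, in which case the beam idles
#' once the segment MU completes (total MU is conserved exactly). At each
#' bin change the delivered rate ramps linearly from the old to the new
#' bin over the switching time, centred on the control point; the ramp
#' integrates to the same MU as an instant switch, so control-point MU
#' stays exact while the fluence near the junction is perturbed over a
#' distance of leaf speed times switching time -- the mechanism behind
#' junction under- and over-dose at dose-rate changes. Programmed leaf
#' direction reversals receive the over-travel excursion of the error
#' model, and systematic leaf offsets apply throughout.
#'
#' @param plan A `vmat_plan`.
#' @param limits A [machine_limits()] object.
#' @param errors An [error_model()].
#' @param dt Sampling step, seconds (default 0.01; control-point and
#'   bin-change instants are always sampled exactly).
#' @return A `delivery_trace`: list with `samples` (tibble of time, cum_mu,
#'   gantry, jaw positions, active bin), `bank_a`/`bank_b` (sample x 40
#'   leaf position matrices, cm), `events` (per-segment bin selections,
#'   caps and lags) and provenance.
#' @examples
#' tr <- simulate_delivery(gen_speed_limit_test("mlc", 10))
#' max(tr$samples$time) # 5 s: 50 MU at 10 MU/s
#' @export
simulate_delivery <- function(plan, limits = machine_limits(),
                              errors = error_model(), dt = 0.01) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  cps <- plan$control_points
  n_cp <- nrow(cps)
  la <- leaf_bank_cols("a")
  lb <- leaf_bank_cols("b")
  A_cp <- as.matrix(cps[, la])
  B_cp <- as.matrix(cps[, lb])
  bins <- build_bin_table(limits$dr_max, limits$n_dr_bins)
  lag <- if (is.na(errors$dr_switch_lag)) {
    limits$dr_switch_time
  } else {
    errors$dr_switch_lag
  }
  delta <- errors$reversal_overtravel

  # pass 1: per-segment kinematics, bin selection and durations
  info <- list()
  for (i in seq_len(n_cp - 1L)) {
    seg <- segment_kinematics(cps[i, ], cps[i + 1L, ])
    if (seg$d_mu <= 0 && seg$max_leaf_travel <= 0 && seg$jaw_travel <= 0 &&
        seg$d_theta <= 0) {
      next
    }
    sel <- select_bin(seg, limits)
    rate <- mu_per_min_to_s(bins$exact[sel$bin + 1L])
    t_nominal <- seg$d_mu / rate
    t_motion <- max(
      t_nominal,
      seg$max_leaf_travel / limits$mlc_speed_max,
      seg$jaw_travel / limits$jaw_speed_max,
      seg$d_theta / limits$gantry_speed_max
    )
    t_seg <- max(t_motion, t_nominal)
    info[[length(info) + 1L]] <- list(
      i = i, d_mu = seg$d_mu, sel = sel, rate = rate,
      t_nominal = t_nominal, t_motion = t_motion, t_seg = t_seg,
      # delivered rate at the segment end: zero when the beam idles after
      # the MU completes on a speed-capped segment
      rate_end = if (t_seg > t_nominal + 1e-12) 0 else rate
    )
  }
  n_seg <- length(info)
  if (n_seg == 0L) stop("plan contains no deliverable segment", call. = FALSE)

  # dose-rate switching: at each bin change the delivered rate ramps
  # linearly from the old to the new bin over the switch time, centred on
  # the control point. The ramp integrates to the same MU as the step, so
  # cumulative MU at every control point is exact; the fluence artefact is
  # confined to (leaf speed x switch time) around the junction.
  h_at <- numeric(n_seg + 1L) # blend half-width at each segment boundary
  for (b in seq_len(n_seg - 1L)) {
    if (info[[b]]$sel$bin != info[[b + 1L]]$sel$bin && lag > 0) {
      h_at[b + 1L] <- min(lag / 2, info[[b]]$t_seg / 2, info[[b + 1L]]$t_seg / 2)
    }
  }

  t_now <- 0
  prev_vel_a <- rep(0, N_PAIRS)
  prev_vel_b <- rep(0, N_PAIRS)
  out_t <- list()
  out_mu <- list()
  out_A <- list()
  out_B <- list()
  out_g <- list()
  out_jl <- list()
  out_jr <- list()
  out_bin <- list()
  events <- list()

  for (k in seq_len(n_seg)) {
    sg <- info[[k]]
    i <- sg$i
    t_seg <- sg$t_seg
    t_motion <- sg$t_motion
    h0 <- h_at[k]       # blend into this segment at its start
    h1 <- h_at[k + 1L]  # blend out of this segment at its end

    da <- A_cp[i + 1L, ] - A_cp[i, ]
    db <- B_cp[i + 1L, ] - B_cp[i, ]
    vel_a <- if (t_motion > 0) da / t_motion else rep(0, N_PAIRS)
    vel_b <- if (t_motion > 0) db / t_motion else rep(0, N_PAIRS)

    # over-travel excursions where a leaf's velocity flips sign at this
    # control point
    bump_knots <- numeric(0)
    rev_a <- delta > 0 & prev_vel_a * vel_a < -1e-12
    rev_b <- delta > 0 & prev_vel_b * vel_b < -1e-12
    if (any(rev_a) || any(rev_b)) {
      v_in <- abs(c(prev_vel_a[rev_a], prev_vel_b[rev_b]))
      bump_knots <- unique(c(delta / v_in, 2 * delta / v_in))
      bump_knots <- bump_knots[bump_knots < t_seg]
    }

    tt <- unique(sort(c(
      seq(0, t_seg, by = dt), sg$t_nominal, t_motion, t_seg, bump_knots,
      h0, t_seg - h1
    )))
    tt <- tt[tt >= 0 & tt <= t_seg + 1e-12]
    tt <- tt[c(TRUE, diff(tt) > 1e-9)] # collapse sub-ns knot duplicates

    # cumulative MU: constant bin rate until the segment MU completes,
    # then beam idle (speed-capped segments), plus the boundary ramps
    mu_t <- pmin(sg$d_mu, sg$rate * tt)
    if (h0 > 0) {
      r1 <- info[[k - 1L]]$rate_end
      u <- tt[tt <= h0]
      mu_t[tt <= h0] <- mu_t[tt <= h0] +
        (sg$rate - r1) * (h0 - u)^2 / (4 * h0)
    }
    if (h1 > 0) {
      r2 <- info[[k + 1L]]$rate
      u <- tt[tt >= t_seg - h1] - t_seg
      mu_t[tt >= t_seg - h1] <- mu_t[tt >= t_seg - h1] +
        (r2 - sg$rate_end) * (h1 - abs(u))^2 / (4 * h1)
    } else {
      mu_t[length(mu_t)] <- sg$d_mu # exact at an unblended boundary
    }

    frac <- if (t_motion > 0) pmin(tt, t_motion) / t_motion else rep(1, length(tt))
    A_s <- outer(rep(1, length(tt)), A_cp[i, ]) + outer(frac, da)
    B_s <- outer(rep(1, length(tt)), B_cp[i, ]) + outer(frac, db)

    bump_profile <- function(v_in_j, v_out_j) {
      tau <- delta / abs(v_in_j)
      peak <- delta * (1 + abs(v_out_j) / abs(v_in_j))
      up <- pmin(tt, tau) / tau * peak
      down <- pmax(0, 1 - (tt - tau) / tau) * peak
      ifelse(tt <= tau, up, pmin(up, down)) * sign(v_in_j)
    }
    if (any(rev_a)) {
      for (j in which(rev_a)) A_s[, j] <- A_s[, j] + bump_profile(prev_vel_a[j], vel_a[j])
    }
    if (any(rev_b)) {
      for (j in which(rev_b)) B_s[, j] <- B_s[, j] + bump_profile(prev_vel_b[j], vel_b[j])
    }

    g_s <- cps$gantry[i] + frac * (cps$gantry[i + 1L] - cps$gantry[i])
    jl_s <- cps$jaw_l[i] + frac * (cps$jaw_l[i + 1L] - cps$jaw_l[i])
    jr_s <- cps$jaw_r[i] + frac * (cps$jaw_r[i + 1L] - cps$jaw_r[i])

    keep <- if (length(out_t) == 0L) seq_along(tt) else seq_along(tt)[-1]
    out_t <- c(out_t, list(t_now + tt[keep]))
    out_mu <- c(out_mu, list(cps$cum_mu[i] + mu_t[keep]))
    out_A <- c(out_A, list(A_s[keep, , drop = FALSE]))
    out_B <- c(out_B, list(B_s[keep, , drop = FALSE]))
    out_g <- c(out_g, list(g_s[keep]))
    out_jl <- c(out_jl, list(jl_s[keep]))
    out_jr <- c(out_jr, list(jr_s[keep]))
    out_bin <- c(out_bin, list(rep(sg$sel$bin, length(keep))))
    events <- c(events, list(tibble::tibble(
      segment = i, time_start = t_now, duration = t_seg,
      bin = sg$sel$bin, limiting_axis = sg$sel$limiting_axis,
      capped = sg$sel$capped || t_motion > sg$t_nominal + 1e-12,
      lag = if (h0 > 0) 2 * h0 else 0,
      n_reversals = sum(rev_a) + sum(rev_b)
    )))

    t_now <- t_now + t_seg
    prev_vel_a <- vel_a
    prev_vel_b <- vel_b
  }

  A_all <- do.call(rbind, out_A)
  B_all <- do.call(rbind, out_B)
  n_s <- nrow(A_all)
  A_all <- A_all + offset_matrix(errors$leaf_offset, n_s, "a")
  B_all <- B_all + offset_matrix(errors$leaf_offset, n_s, "b")

  samples <- tibble::tibble(
    time = unlist(out_t), cum_mu = unlist(out_mu), gantry = unlist(out_g),
    jaw_l = unlist(out_jl), jaw_r = unlist(out_jr),
    active_bin = as.integer(unlist(out_bin))
  )
  structure(
    list(
      samples = samples, bank_a = A_all, bank_b = B_all,
      events = dplyr::bind_rows(events),
      plan_name = plan$name, limits = limits, errors = errors, dt = dt,
      total_mu = max(cps$cum_mu)
    ),
    class = "delivery_trace"
  )
}

#' @export
print.delivery_trace <- function(x, ...) {
  cat(sprintf(
    "<delivery_trace> %s: %.1f MU in %.2f s, %d samples, bins %s\n",
    x$plan_name, max(x$samples$cum_mu), max(x$samples$time),
    nrow(x$samples), paste(sort(unique(x$samples$active_bin)), collapse = ",")
  ))
  invisible(x)
}

#' Tidy a delivery trace into its sample table
#'
#' @param x A `delivery_trace`.
#' @param ... Unused.
#' @return The per-sample tibble augmented with the extreme leaf positions
#'   (`leaf_a_min`, `leaf_b_max`) per sample.
#' @method tidy delivery_trace
#' @export
tidy.delivery_trace <- function(x, ...) {
  dplyr::mutate(
    x$samples,
    leaf_a_min = apply(x$bank_a, 1, min),
    leaf_b_max = apply(x$bank_b, 1, max)
  )
}
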