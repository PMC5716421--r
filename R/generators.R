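#' @title Test-plan generators
#' @description Constructors for the dynamic commissioning test deliveries:
#'   picket fences (with optional intentional errors), single-axis
#'   maximum-speed fields, matched dose-rate/gantry-speed strips, MLC-speed
#'   strips, rapid leaf reversals, dose-rate change junctions and utility
#'   fields. All geometry is in cm at the isocenter plane; MU values are
#'   quantized to the machine's MU entry resolution at emission.
#' @name plan_generators
NULL

# interpolate a piecewise-linear pair trajectory (breakpoints in MU) onto a
# common cumulative-MU grid
interp_traj <- function(traj, mu_grid) {
  list(
    a = stats::approx(traj$mu, traj$a, xout = mu_grid, rule = 2)$y,
    b = stats::approx(traj$mu, traj$b, xout = mu_grid, rule = 2)$y
  )
}

# assemble a control-point tibble from 40 per-pair trajectories given on
# possibly different MU breakpoints
assemble_cps <- function(trajs, gantry_fun, jaw_fun = NULL, coll = 0,
                         dr_cap = NA_real_, mu_resolution = 0.1) {
  mu_grid <- sort(unique(quantize_mu(
    unlist(lapply(trajs, function(t) t$mu)),
    mu_resolution
  )))
  pos <- lapply(trajs, interp_traj, mu_grid = mu_grid)
  A <- vapply(pos, `[[`, numeric(length(mu_grid)), "a")
  B <- vapply(pos, `[[`, numeric(length(mu_grid)), "b")
  if (is.null(jaw_fun)) {
    jaw_l <- apply(A, 1, min)
    jaw_r <- apply(B, 1, max)
  } else {
    jw <- jaw_fun(mu_grid)
    jaw_l <- jw$l
    jaw_r <- jw$r
  }
  cps <- tibble::as_tibble(cbind(
    data.frame(cum_mu = mu_grid, gantry = gantry_fun(mu_grid)),
    stats::setNames(as.data.frame(A), leaf_bank_cols("a")),
    stats::setNames(as.data.frame(B), leaf_bank_cols("b")),
    data.frame(jaw_l = jaw_l, jaw_r = jaw_r, coll = coll, dr_cap = dr_cap)
  ))
  cps
}

# leaf pairs whose 1-cm rows fall inside a field of the given height (cm),
# centred on the beam axis
pairs_in_field <- function(height) {
  centre <- seq_len(N_PAIRS) - (N_PAIRS + 1) / 2 # pair centres, cm
  which(abs(centre) <= height / 2 - 0.4999)
}

# parked leaves sit closed at the extreme of the travel range
park_a <- function() -(LEAF_POS_MAX - 0.5)

#' Generate a dynamic picket-fence plan
#'
#' A picket fence is a sweeping-gap delivery in which, at each picket
#' position, the leading leaf advances across the picket strip while the
#' trailing leaf then pauses over it, so the strip stays open roughly twice
#' as long as the background and images as a narrow bright line. One or
#' both leaves move continuously at every instant. Intentional errors
#' (a widened picket strip, or a picket shifted along the leaf travel
#' direction) can be programmed on individual leaf pairs; when any error is
#' present the default gap widens from 5 mm to 6 mm so that adjacent
#' leaves never violate the minimum gap.
#'
#' @param field_size Square field side, cm (default 25).
#' @param gap Sweeping gap, cm; default 0.5, or 0.6 when `errors` given.
#' @param picket_positions Picket centres along the cross-plane axis, cm.
#' @param picket_width Enhanced strip width, cm (default 0.1 = 1 mm).
#' @param arc Arc span in degrees (0 = static gantry).
#' @param gantry_start Starting gantry angle, degrees.
#' @param errors Optional list of error specs, each a list with `pair`
#'   (leaf pair index) and either `widen_to` (new strip width, cm) or
#'   `shift` (picket displacement, cm).
#' @param leaf_speed Sweep speed, cm/s (default 1).
#' @param limits A [machine_limits()] object.
#' @return A `vmat_plan` with picket layout metadata in `$meta`.
#' @examples
#' plan <- gen_picket_fence()
#' glance(plan)
#' @export
gen_picket_fence <- function(field_size = 25, gap = NULL,
                             picket_positions = seq(-9, 9, by = 3),
                             picket_width = 0.1, arc = 0, gantry_start = 0,
                             errors = NULL, leaf_speed = 1,
                             limits = machine_limits()) {
  if (is.null(gap)) gap <- if (length(errors) > 0) 0.6 else 0.5
  if (gap < limits$min_gap - 1e-9) {
    stop("gap below the machine minimum gap", call. = FALSE)
  }
  if (picket_width >= gap) {
    stop("picket_width must be smaller than the gap", call. = FALSE)
  }
  pk <- sort(picket_positions)
  if (length(pk) > 0) {
    if (any(abs(pk) > field_size / 2)) {
      stop("picket positions must lie inside the field", call. = FALSE)
    }
    if (length(pk) > 1 && min(diff(pk)) <= gap + picket_width) {
      stop("picket spacing smaller than the sweeping gap", call. = FALSE)
    }
  }
  err_pairs <- vapply(errors, function(e) as.integer(e$pair), integer(1))
  if (anyDuplicated(err_pairs)) {
    stop("at most one error per leaf pair", call. = FALSE)
  }

  rate <- mu_per_min_to_s(limits$dr_max) # run at the top bin
  v <- leaf_speed
  x_lo <- -field_size / 2
  x_hi <- field_size / 2

  pair_traj <- function(centres, width) {
    # breakpoints (mu, a, b) for one pair; a = trailing, b = leading.
    # At each picket the leading leaf pauses at the strip's far edge and,
    # once the trailing leaf reaches the near edge, the trailing leaf
    # pauses for the same time -- so only the strip itself stays open
    # longer (by width / speed) and one leaf is always moving.
    t <- 0
    a <- x_lo - gap
    b <- x_lo
    rows <- list(c(t, a, b))
    pause <- width / v
    for (p in centres) {
      s0 <- p - width / 2
      s1 <- p + width / 2
      # leading leaf reaches the far edge, pauses there
      dt <- (s1 - b) / v
      t <- t + dt
      a <- a + dt * v
      b <- s1
      rows <- c(rows, list(c(t, a, b)))
      t <- t + pause
      a <- a + width
      rows <- c(rows, list(c(t, a, b)))
      # trailing leaf reaches the near edge, pauses for the same time
      dt <- (s0 - a) / v
      t <- t + dt
      a <- s0
      b <- b + dt * v
      rows <- c(rows, list(c(t, a, b)))
      t <- t + pause
      b <- b + width
      rows <- c(rows, list(c(t, a, b)))
    }
    dt <- (x_hi - a) / v
    t <- t + dt
    rows <- c(rows, list(c(t, x_hi, b + dt * v)))
    m <- do.call(rbind, rows)
    tibble::tibble(mu = m[, 1] * rate, a = m[, 2], b = m[, 3])
  }

  base <- pair_traj(pk, picket_width)
  trajs <- rep(list(base), N_PAIRS)
  for (e in errors) {
    centres <- pk
    width <- picket_width
    if (!is.null(e$widen_to)) width <- e$widen_to
    if (!is.null(e$shift)) centres <- pk + e$shift
    trajs[[e$pair]] <- pair_traj(centres, width)
  }
  # pairs finish at different MU when errors lengthen events: hold at end
  total_mu <- max(vapply(trajs, function(t) max(t$mu), numeric(1)))
  trajs <- lapply(trajs, function(t) {
    if (max(t$mu) < total_mu - 1e-9) {
      t <- dplyr::bind_rows(t, tibble::tibble(
        mu = total_mu, a = t$a[nrow(t)], b = t$b[nrow(t)]
      ))
    }
    t
  })

  total_mu_q <- quantize_mu(total_mu, limits$mu_resolution)
  gantry_fun <- function(mu) gantry_start + arc * mu / total_mu_q
  cps <- assemble_cps(trajs, gantry_fun,
    jaw_fun = function(mu) list(l = rep(x_lo - gap, length(mu)),
                                r = rep(x_hi + gap, length(mu))),
    mu_resolution = limits$mu_resolution
  )
  vmat_plan(
    name = if (length(errors) > 0) "picket_fence_errors" else "picket_fence",
    control_points = cps,
    meta = list(
      picket_positions = pk, picket_width = picket_width, gap = gap,
      leaf_speed = v, arc = arc,
      errors = lapply(errors, function(e) e[c("pair", "widen_to", "shift")])
    ),
    notes = sprintf(
      "%d pickets, %.1f mm strips, %.0f mm gap, %s gantry",
      length(pk), picket_width * 10, gap * 10,
      if (arc > 0) sprintf("%g deg arc", arc) else "static"
    )
  )
}

#' Generate a single-axis maximum-speed consistency test
#'
#' A single dynamic segment whose MU is chosen so that the named axis must
#' run at exactly its configured maximum when the delivery runs at the top
#' dose-rate bin: `MU = DRmax * travel / v_max` (dose rate in MU/s). If the
#' MU is lowered, the axis would have to over-speed and the controller must
#' drop a dose-rate bin -- the observable used to verify the configured
#' maximum for internal consistency.
#'
#' @param axis One of `"mlc"`, `"jaw"`, `"gantry"`.
#' @param travel Axis travel: cm for `mlc`/`jaw`, degrees for `gantry`.
#' @param limits A [machine_limits()] object.
#' @param mu_override Optional MU to use instead of the computed value.
#' @param gap Sweeping gap for the MLC variant, cm (default 0.8).
#' @param field_size Field side, cm.
#' @return A `vmat_plan`.
#' @examples
#' glance(gen_speed_limit_test("mlc", 10)) # 50 MU
#' @export
gen_speed_limit_test <- function(axis = c("mlc", "jaw", "gantry"),
                                 travel = NULL, limits = machine_limits(),
                                 mu_override = NULL, gap = 0.8,
                                 field_size = 10) {
  axis <- match.arg(axis)
  if (is.null(travel)) travel <- if (axis == "gantry") 180 else 10
  if (travel <= 0) stop("travel must be positive", call. = FALSE)
  rate <- mu_per_min_to_s(limits$dr_max)
  v_max <- switch(axis,
    mlc = limits$mlc_speed_max,
    jaw = limits$jaw_speed_max,
    gantry = limits$gantry_speed_max
  )
  mu <- if (is.null(mu_override)) {
    quantize_mu(rate * travel / v_max, limits$mu_resolution)
  } else {
    mu_override
  }
  half <- field_size / 2
  open_pairs <- pairs_in_field(field_size)
  a0 <- rep(park_a(), N_PAIRS)
  b0 <- rep(park_a(), N_PAIRS)

  if (axis == "mlc") {
    a0[open_pairs] <- -half
    b0[open_pairs] <- -half + gap
    a1 <- a0
    b1 <- b0
    a1[open_pairs] <- -half + travel
    b1[open_pairs] <- -half + travel + gap
    cps <- dplyr::bind_rows(
      control_point(0, a = a0, b = b0, jaw_l = -half - gap, jaw_r = half + gap),
      control_point(mu, a = a1, b = b1, jaw_l = -half - gap, jaw_r = half + gap)
    )
  } else if (axis == "jaw") {
    a0[open_pairs] <- -half
    b0[open_pairs] <- half
    cps <- dplyr::bind_rows(
      control_point(0, a = a0, b = b0, jaw_l = -half, jaw_r = -half + 0),
      control_point(mu, a = a0, b = b0, jaw_l = -half, jaw_r = -half + travel)
    )
  } else {
    a0[open_pairs] <- -half
    b0[open_pairs] <- half
    cps <- dplyr::bind_rows(
      control_point(0, gantry = 0, a = a0, b = b0),
      control_point(mu, gantry = travel, a = a0, b = b0)
    )
  }
  vmat_plan(
    name = paste0("speed_limit_", axis), control_points = cps,
    meta = list(axis = axis, travel = travel, gap = gap, planned_mu = mu),
    notes = sprintf("%s max-speed consistency test: %g units in %g MU", axis, travel, mu)
  )
}

default_dr_gs_factors <- function() {
  tibble::tibble(
    dr_factor = c(1 / 32, 1 / 16, 1 / 8, 1 / 4, 1 / 2, 1, 1.2, 1),
    gs_factor = c(1 / 32, 1 / 16, 1 / 8, 1 / 4, 1 / 2, 1, 1, 1.2)
  )
}

#' Generate the dose-rate : gantry-speed strip test
#'
#' Eight 3 cm strips, each delivered with a prescribed (dose rate, gantry
#' speed) pair; the matched pairs run from max/32 : max/32 up to max : max,
#' and the final two strips deliberately plan 1.2x the maximum dose rate or
#' gantry speed to confirm the controller still delivers the correct dose.
#' The MU per strip is constant (`mu_strip`), as are the MU delivered while
#' translating between strips: the 3 cm slit moves at 0.75x the maximum
#' leaf speed, so each move takes `3 / (0.75 v_max)` s, at a fixed between-
#' strip dose rate of max/8 (which keeps the MU-per-degree floor
#' satisfied: `(DRmax/8) / GSmax = 0.208 MU/deg` at full gantry speed).
#' Each strip's arc span follows from `mu_strip * GS / DR`; matched strips
#' all span the same angle. The slit dwells on a strip while the gantry
#' arcs (the imaging detector is gantry-mounted, so the image is static in
#' the gantry frame) and the aperture slides in from one strip width
#' before the first strip and out one width after the last.
#'
#' @param limits A [machine_limits()] object.
#' @param mu_strip MU per strip (default 20).
#' @param factor_pairs Tibble with columns `dr_factor`, `gs_factor`
#'   (fractions of the maxima; may exceed 1). Default: the standard eight.
#' @param strip_width Strip width, cm (default 3).
#' @param x_start Left edge of the first strip, cm.
#' @param gantry_start Starting gantry angle, degrees.
#' @param max_arc Total arc must stay below this span (degrees).
#' @return A `vmat_plan` with one `strip_specs` row per strip.
#' @examples
#' plan <- gen_dr_gs_strip_test()
#' plan$strip_specs[, c("index", "dr_factor", "gs_factor", "arc_span")]
#' @export
gen_dr_gs_strip_test <- function(limits = machine_limits(), mu_strip = 20,
                                 factor_pairs = default_dr_gs_factors(),
                                 strip_width = 3, x_start = -12,
                                 gantry_start = 0, max_arc = 358) {
  n <- nrow(factor_pairs)
  rate_max <- mu_per_min_to_s(limits$dr_max)
  move_v <- 0.75 * limits$mlc_speed_max
  move_dr_f <- 1 / 8
  move_t <- strip_width / move_v
  move_mu <- quantize_mu(move_t * rate_max * move_dr_f, limits$mu_resolution)
  if (mu_strip <= move_mu) {
    stop("mu_strip must exceed the between-strip MU (", move_mu, ")", call. = FALSE)
  }

  edges <- x_start + strip_width * (0:n)
  gs <- pmin(factor_pairs$gs_factor, 1) * limits$gantry_speed_max # deliverable
  gs_planned <- factor_pairs$gs_factor * limits$gantry_speed_max
  dr_planned <- factor_pairs$dr_factor * rate_max
  arc_strip <- mu_strip * gs_planned / dr_planned
  arc_moves <- move_t * c(gs[1], gs[-n]) # lead-in at strip 1's speed
  arc_out <- move_t * gs[n]
  total_arc <- sum(arc_strip) + sum(arc_moves) + arc_out
  if (total_arc >= max_arc) {
    stop(sprintf(
      "total arc %.2f deg reaches the %g deg limit; lower mu_strip",
      total_arc, max_arc
    ), call. = FALSE)
  }

  mu <- 0
  th <- gantry_start
  slit <- function(mu, th, a, cap) {
    control_point(mu,
      gantry = th, a = a, b = a + strip_width,
      jaw_l = a, jaw_r = a + strip_width, dr_cap = cap
    )
  }
  rows <- list(slit(0, th, edges[1] - strip_width, NA_real_))
  for (k in seq_len(n)) {
    # translate onto strip k
    mu <- mu + move_mu
    th <- th + arc_moves[k]
    rows <- c(rows, list(slit(mu, th, edges[k], move_dr_f)))
    # dwell on strip k
    mu <- mu + mu_strip
    th <- th + arc_strip[k]
    rows <- c(rows, list(slit(mu, th, edges[k], min(factor_pairs$dr_factor[k], 1))))
  }
  mu <- mu + move_mu
  th <- th + arc_out
  rows <- c(rows, list(slit(mu, th, edges[n + 1], move_dr_f)))
  cps <- dplyr::bind_rows(rows)
  cps$cum_mu <- quantize_mu(cps$cum_mu, limits$mu_resolution)

  specs <- tibble::tibble(
    index = seq_len(n),
    x_start = edges[seq_len(n)], x_end = edges[seq_len(n) + 1],
    dr_factor = factor_pairs$dr_factor, gs_factor = factor_pairs$gs_factor,
    mlc_speed_factor = NA_real_, planned_mu = mu_strip,
    traversal_count = NA_real_, arc_span = arc_strip
  )
  vmat_plan(
    name = "dr_gs_strips", control_points = cps, strip_specs = specs,
    meta = list(
      mode = "dwell", slit_width = strip_width, move_speed = move_v,
      move_dr_factor = move_dr_f, move_mu = move_mu, total_arc = total_arc
    ),
    notes = sprintf(
      "%d DR:GS strips, %g MU each, total arc %.2f deg", n, mu_strip, total_arc
    )
  )
}

default_mlc_speed_factors <- function() {
  f <- c(1 / 32, 1 / 16, 1 / 8, 1 / 4, 1 / 2, 1, 1.2)
  tibble::tibble(mlc_speed_factor = f, dr_factor = f)
}

# shared sweeping-gap builder: trailing edge A crosses zones of differing
# speed and prescribed dose rate under a constant gantry speed
build_sweep_plan <- function(zone_edges, zone_v, zone_dr_f, gap, gs_const,
                             limits, name, gantry_start = 0) {
  rate_max <- mu_per_min_to_s(limits$dr_max)
  nz <- length(zone_v)
  stopifnot(length(zone_edges) == nz + 1, length(zone_dr_f) == nz)
  d_mu <- diff(zone_edges) * (zone_dr_f * rate_max) / zone_v
  t_seg <- d_mu / (zone_dr_f * rate_max)
  cum <- cumsum(c(0, d_mu))
  th <- gantry_start + cumsum(c(0, t_seg)) * gs_const
  a <- zone_edges
  rows <- lapply(seq_len(nz + 1), function(i) {
    control_point(cum[i],
      gantry = th[i], a = a[i], b = a[i] + gap,
      jaw_l = min(zone_edges), jaw_r = max(zone_edges) + gap,
      dr_cap = if (i == 1) NA_real_ else min(zone_dr_f[i - 1], 1)
    )
  })
  cps <- dplyr::bind_rows(rows)
  cps$cum_mu <- quantize_mu(cps$cum_mu, limits$mu_resolution)
  list(cps = cps, d_mu = d_mu, t_seg = t_seg, theta = th)
}

#' Generate the MLC-speed strip test
#'
#' A sweeping 8 mm gap crosses seven 3 cm strips, each delivered with a
#' prescribed (MLC speed, dose rate) pair scaling together from max/32 to
#' the maximum, plus a final strip planned at 1.2x both (the controller
#' delivers it at the maxima, with the gantry correspondingly slower by the
#' factor 1.2). Scaling speed and dose rate together keeps the dose per
#' strip constant: `MU = width * DRmax / v_max` per strip. The gantry speed
#' is constant, set by the MU-per-degree floor at the lowest strip dose
#' rate: `GS = (DRmax/32) / 0.1 MU/deg`. Lateral 1.5 cm strips on both
#' sides are swept to the same dose so the field matches the open fields
#' used for normalization.
#'
#' A 5 mm gap is refused: driving the MLC near maximum speed with the
#' minimum gap is known to deliver poorly.
#'
#' @param limits A [machine_limits()] object.
#' @param factor_pairs Tibble with columns `mlc_speed_factor`, `dr_factor`.
#' @param gap Sweeping gap, cm (default 0.8; must exceed the machine
#'   minimum).
#' @param strip_width Strip width, cm (default 3).
#' @param lateral_width Width of the edge strips, cm (default 1.5).
#' @param lateral_factor Speed/dose-rate factor for the edge strips.
#' @return A `vmat_plan` with `strip_specs` for the seven test strips.
#' @examples
#' plan <- gen_mlc_speed_strip_test()
#' unique(plan$strip_specs$planned_mu) # 15 MU per strip
#' @export
gen_mlc_speed_strip_test <- function(limits = machine_limits(),
                                     factor_pairs = default_mlc_speed_factors(),
                                     gap = 0.8, strip_width = 3,
                                     lateral_width = 1.5,
                                     lateral_factor = 0.5) {
  if (gap <= limits$min_gap + 1e-9) {
    stop("gap must exceed the machine minimum gap for this test", call. = FALSE)
  }
  n <- nrow(factor_pairs)
  rate_max <- mu_per_min_to_s(limits$dr_max)
  gs_const <- (rate_max * min(factor_pairs$dr_factor)) / limits$mu_per_degree_min

  width_total <- n * strip_width + 2 * lateral_width
  x0 <- -width_total / 2
  strip_edges <- x0 + lateral_width + strip_width * (0:n)
  zone_edges <- c(x0 - gap, x0, strip_edges, x0 + width_total)
  v_strip <- pmin(factor_pairs$mlc_speed_factor, 1) * limits$mlc_speed_max
  v_lat <- lateral_factor * limits$mlc_speed_max
  zone_v <- c(v_lat, v_lat, v_strip, v_lat)
  zone_f <- c(
    lateral_factor, lateral_factor,
    pmin(factor_pairs$dr_factor, 1), lateral_factor
  )
  built <- build_sweep_plan(
    zone_edges, zone_v, zone_f, gap, gs_const, limits,
    name = "mlc_speed_strips"
  )
  specs <- tibble::tibble(
    index = seq_len(n),
    x_start = strip_edges[seq_len(n)], x_end = strip_edges[seq_len(n) + 1],
    dr_factor = factor_pairs$dr_factor, gs_factor = NA_real_,
    mlc_speed_factor = factor_pairs$mlc_speed_factor,
    planned_mu = strip_width * (factor_pairs$dr_factor * rate_max) /
      (factor_pairs$mlc_speed_factor * limits$mlc_speed_max),
    traversal_count = 1,
    arc_span = built$t_seg[2 + seq_len(n)] * gs_const
  )
  vmat_plan(
    name = "mlc_speed_strips", control_points = built$cps, strip_specs = specs,
    meta = list(
      mode = "sweep", gap = gap, gantry_speed = gs_const,
      lateral_width = lateral_width, lateral_factor = lateral_factor
    ),
    notes = sprintf(
      "%d MLC-speed strips, gap %.1f mm, constant GS %.3f deg/s",
      n, gap * 10, gs_const
    )
  )
}

#' Generate the rapid leaf-reversal test
#'
#' A constant-speed sweeping gap zigzags across five strips so that the
#' dose per strip grows with the number of gap traversals, with reversal
#' excursions at the strip junctions and a repeated oscillation near the
#' right-hand edge. One plan is generated per leaf-speed factor; the
#' slowest (default 0.18, i.e. 0.36 cm/s) serves as the reference with
#' negligible over-travel. The dose rate is prescribed at half maximum.
#'
#' The junction centres default to -5.6, -1.6, 3.6 and 7.6 cm with the
#' oscillation centred at 10.6 cm. The centre-of-strip traversal counts
#' realized by the zigzag (1, 3, 3, 3, 9) are recorded per strip in
#' `strip_specs$traversal_count`, and every programmed direction change is
#' recorded in `$meta$turns` with the aperture edge where over-travel
#' overdose would appear and the local nominal pass count -- the inputs
#' [reversal_analysis()] needs to invert the over-travel magnitude.
#'
#' @param limits A [machine_limits()] object.
#' @param speed_factors Leaf speeds as fractions of the maximum; one plan
#'   per factor.
#' @param junctions Junction centres, cm.
#' @param x_left,x_right Outer strip edges, cm.
#' @param osc_centre Centre of the repeated-reversal oscillation, cm.
#' @param osc_cycles Number of full back-and-forth cycles there.
#' @param gap Sweeping gap, cm (default 0.8).
#' @param dr_factor Prescribed dose-rate fraction (default 0.5).
#' @return A named list of `vmat_plan`s, one per speed factor (names like
#'   `"v1.00"`), each with strip metadata.
#' @examples
#' plans <- gen_reversal_test(speed_factors = c(1, 0.18))
#' plans$v1.00$strip_specs$traversal_count
#' @export
gen_reversal_test <- function(limits = machine_limits(),
                              speed_factors = c(1, 0.95, 0.90, 0.18),
                              junctions = c(-5.6, -1.6, 3.6, 7.6),
                              x_left = -9.6, x_right = 11.6,
                              osc_centre = 10.6, osc_cycles = 4,
                              gap = 0.8, dr_factor = 0.5) {
  j <- junctions
  osc_lo <- osc_centre - 2
  way <- c(
    x_left - gap / 2,
    j[2], j[1], j[3], j[2], j[4], j[3],
    rep(c(osc_centre, osc_lo), osc_cycles),
    x_right + gap / 2
  )
  seg_dir <- sign(diff(way))
  # direction changes (turns): waypoint index i is a turn when the path
  # reverses there; over-travel overshoots past the leading aperture edge
  turn_idx <- which(seg_dir[-1] != seg_dir[-length(seg_dir)]) + 1L
  passes_at <- function(x) {
    sum(pmin(way[-1], way[-length(way)]) < x & x < pmax(way[-1], way[-length(way)]))
  }
  turns <- tibble::tibble(
    position = way[turn_idx],
    direction = seg_dir[turn_idx - 1L],
    edge = way[turn_idx] + seg_dir[turn_idx - 1L] * gap / 2,
    local_passes = vapply(
      way[turn_idx] + seg_dir[turn_idx - 1L] * (gap / 2 + 0.01),
      passes_at, numeric(1)
    )
  )
  strip_edges <- c(x_left, j, x_right)
  centres <- (strip_edges[-1] + strip_edges[-length(strip_edges)]) / 2
  counts <- vapply(centres, passes_at, numeric(1))

  rate <- dr_factor * mu_per_min_to_s(limits$dr_max)
  make_plan <- function(f) {
    v <- f * limits$mlc_speed_max
    d_mu <- abs(diff(way)) * rate / v
    cum <- quantize_mu(cumsum(c(0, d_mu)), limits$mu_resolution)
    rows <- lapply(seq_along(way), function(i) {
      control_point(cum[i],
        a = way[i] - gap / 2, b = way[i] + gap / 2,
        jaw_l = min(way) - gap, jaw_r = max(way) + gap,
        dr_cap = if (i == 1) NA_real_ else dr_factor
      )
    })
    specs <- tibble::tibble(
      index = seq_along(centres),
      x_start = strip_edges[-length(strip_edges)], x_end = strip_edges[-1],
      dr_factor = dr_factor, gs_factor = NA_real_, mlc_speed_factor = f,
      planned_mu = NA_real_, traversal_count = counts, arc_span = 0
    )
    vmat_plan(
      name = sprintf("reversal_v%.2f", f),
      control_points = dplyr::bind_rows(rows), strip_specs = specs,
      meta = list(
        gap = gap, leaf_speed = v, speed_factor = f, junctions = j,
        osc_centre = osc_centre, osc_cycles = osc_cycles, turns = turns
      ),
      notes = sprintf(
        "reversal zigzag at %.2f cm/s, %d direction changes", v, nrow(turns)
      )
    )
  }
  plans <- lapply(speed_factors, make_plan)
  names(plans) <- sprintf("v%.2f", speed_factors)
  plans
}

#' Generate the dose-rate change test
#'
#' A constant-speed sweeping gap crosses eight 3 cm strips whose prescribed
#' dose rates step through max/32 up to the maximum in factors of two, with
#' the last two strips forming the extreme max/32 -> max jump (the
#' decrease variant reverses each step). Fluence per strip is proportional
#' to its dose rate; the junctions between strips probe how quickly the
#' controller settles on a new dose-rate bin. The gantry speed is constant,
#' set by the MU-per-degree floor at the lowest dose rate (3.125 deg/s for
#' the defaults). A reference plan identical except for a slow leaf speed
#' (default 0.25 cm/s) is returned alongside the test plan for
#' normalization.
#'
#' @param direction `"increase"` or `"decrease"`.
#' @param limits A [machine_limits()] object.
#' @param mlc_speed_factor Test sweep speed as a fraction of maximum
#'   (default 0.5, i.e. 1 cm/s).
#' @param reference_speed Reference sweep speed, cm/s (default 0.25).
#' @param gap Sweeping gap, cm.
#' @param strip_width Strip width, cm.
#' @return A list with elements `test` and `reference`, both `vmat_plan`s.
#' @examples
#' pair <- gen_dr_change_test("increase")
#' pair$test$strip_specs$dr_factor * 32
#' @export
gen_dr_change_test <- function(direction = c("increase", "decrease"),
                               limits = machine_limits(),
                               mlc_speed_factor = 0.5, reference_speed = 0.25,
                               gap = 0.8, strip_width = 3) {
  direction <- match.arg(direction)
  base <- c(1 / 32, 1 / 16, 1 / 8, 1 / 4, 1 / 2, 1)
  fr <- if (direction == "increase") c(base, 1 / 32, 1) else c(rev(base), 1, 1 / 32)
  n <- length(fr)
  rate_max <- mu_per_min_to_s(limits$dr_max)
  gs_const <- (rate_max * min(fr)) / limits$mu_per_degree_min
  x0 <- -n * strip_width / 2
  strip_edges <- x0 + strip_width * (0:n)
  zone_edges <- c(x0 - gap, strip_edges)
  zone_f <- c(fr[1], fr)

  build <- function(v, tag) {
    zone_v <- rep(v, n + 1)
    built <- build_sweep_plan(
      zone_edges, zone_v, zone_f, gap, gs_const, limits,
      name = paste0("dr_", direction)
    )
    specs <- tibble::tibble(
      index = seq_len(n),
      x_start = strip_edges[seq_len(n)], x_end = strip_edges[seq_len(n) + 1],
      dr_factor = fr, gs_factor = NA_real_,
      mlc_speed_factor = v / limits$mlc_speed_max,
      planned_mu = built$d_mu[-1], traversal_count = 1,
      arc_span = built$t_seg[-1] * gs_const
    )
    vmat_plan(
      name = sprintf("dr_%s_%s", direction, tag),
      control_points = built$cps, strip_specs = specs,
      meta = list(
        mode = "sweep", gap = gap, leaf_speed = v, gantry_speed = gs_const,
        direction = direction
      ),
      notes = sprintf(
        "dose-rate %s test, leaf speed %.2f cm/s, GS %.3f deg/s",
        direction, v, gs_const
      )
    )
  }
  list(
    test = build(mlc_speed_factor * limits$mlc_speed_max, "test"),
    reference = build(reference_speed, "reference")
  )
}

#' Generate utility fields
#'
#' Static and simple dynamic fields supporting the other tests: a static
#' open field at a chosen dose-rate bin (used for normalization), static
#' and full-arc monitor-chamber stability deliveries, and the
#' gravity-sensitivity sweep: a 1 cm gap crossing a 23 cm field while a
#' 180 degree arc completes in exactly the sweep time, giving a gantry
#' speed of `180 / (23 / 0.74) = 5.79 deg/s` for the defaults.
#'
#' @param kind One of `"open_field"`, `"static_mu"`, `"arc_mu"`,
#'   `"dmlc_gravity"`.
#' @param limits A [machine_limits()] object.
#' @param field_size Field side (cm): 25 for `open_field`, 10 otherwise.
#' @param mu Delivered MU (`open_field` 100, `static_mu` 36, `arc_mu` 1000).
#' @param dr_factor Dose-rate bin as a fraction of maximum.
#' @param arc Arc span, degrees (`arc_mu` 360, `dmlc_gravity` 180).
#' @param gap Moving gap for `dmlc_gravity`, cm.
#' @param sweep_width Leaf travel for `dmlc_gravity`, cm.
#' @param mlc_speed Sweep speed for `dmlc_gravity`, cm/s.
#' @return A `vmat_plan`.
#' @examples
#' g <- gen_utility_fields("dmlc_gravity")
#' g$meta$gantry_speed # 5.79 deg/s
#' @export
gen_utility_fields <- function(kind = c("open_field", "static_mu", "arc_mu",
                                        "dmlc_gravity"),
                               limits = machine_limits(),
                               field_size = NULL, mu = NULL, dr_factor = 1,
                               arc = NULL, gap = 1, sweep_width = 23,
                               mlc_speed = 0.74) {
  kind <- match.arg(kind)
  rate <- mu_per_min_to_s(limits$dr_max)
  if (kind %in% c("open_field", "static_mu", "arc_mu")) {
    field_size <- field_size %||% if (kind == "open_field") 25 else 10
    mu <- mu %||% switch(kind, open_field = 100, static_mu = 36, arc_mu = 1000)
    arc <- arc %||% if (kind == "arc_mu") 360 else 0
    half <- field_size / 2
    open_pairs <- pairs_in_field(field_size)
    a <- rep(park_a(), N_PAIRS)
    b <- rep(park_a(), N_PAIRS)
    a[open_pairs] <- -half
    b[open_pairs] <- half
    cps <- dplyr::bind_rows(
      control_point(0, gantry = 0, a = a, b = b),
      control_point(mu, gantry = arc, a = a, b = b, dr_cap = dr_factor)
    )
    return(vmat_plan(
      name = sprintf("%s_dr%g", kind, dr_factor), control_points = cps,
      meta = list(kind = kind, field_size = field_size, dr_factor = dr_factor),
      notes = sprintf(
        "%g x %g cm field, %g MU at %g of max DR, %s",
        field_size, field_size, mu, dr_factor,
        if (arc > 0) sprintf("%g deg arc", arc) else "static"
      )
    ))
  }
  # dmlc_gravity: leaf travel equals the sweep width exactly, so the stated
  # MLC speed, arc time and gantry speed are mutually consistent
  arc <- arc %||% 180
  half <- (sweep_width + gap) / 2
  open_pairs <- pairs_in_field(10)
  sweep_t <- sweep_width / mlc_speed
  gantry_speed <- arc / sweep_t
  mu <- quantize_mu(rate * dr_factor * sweep_t, limits$mu_resolution)
  a0 <- rep(park_a(), N_PAIRS)
  b0 <- rep(park_a(), N_PAIRS)
  a0[open_pairs] <- -half
  b0[open_pairs] <- -half + gap
  a1 <- a0
  b1 <- b0
  a1[open_pairs] <- half - gap
  b1[open_pairs] <- half
  cps <- dplyr::bind_rows(
    control_point(0, gantry = 0, a = a0, b = b0,
                  jaw_l = -half - gap, jaw_r = half + gap),
    control_point(mu, gantry = arc, a = a1, b = b1,
                  jaw_l = -half - gap, jaw_r = half + gap,
                  dr_cap = dr_factor)
  )
  vmat_plan(
    name = "dmlc_gravity", control_points = cps,
    meta = list(
      kind = kind, gap = gap, sweep_width = sweep_width,
      mlc_speed = mlc_speed, gantry_speed = gantry_speed, arc = arc
    ),
    notes = sprintf(
      "1 cm gravity gap: %g cm sweep at %g cm/s, %g deg arc at %.2f deg/s",
      sweep_width, mlc_speed, arc, gantry_speed
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
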