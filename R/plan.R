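#' @importFrom rlang .data
NULL

N_PAIRS <- 40L
LEAF_POS_MAX <- 20 # cm, leaf travel range at isocenter

leaf_bank_cols <- function(bank = c("a", "b")) {
  bank <- match.arg(bank)
  sprintf("%s%02d", bank, seq_len(N_PAIRS))
}

#' One control point of a dynamic plan
#'
#' A control point is one row of a VMAT plan: the cumulative MU at which the
#' machine must simultaneously be at a given gantry angle, per-leaf bank
#' positions and backup-jaw positions. Bank A holds the left (trailing)
#' leaves and bank B the right (leading) leaves along the cross-plane axis
#' `x`, positive toward bank B; an open pair satisfies `b - a > 0`.
#'
#' @param cum_mu Cumulative MU (non-negative).
#' @param gantry Gantry angle in degrees. Stored as a continuous real so
#'   that arcs never wrap inside a plan.
#' @param a,b Leaf positions for banks A and B, cm at isocenter; scalars are
#'   recycled to all 40 pairs.
#' @param jaw_l,jaw_r Backup-jaw positions, cm; default to the outermost
#'   leaf position of the matching bank.
#' @param coll Collimator angle, degrees (static; dynamic collimator
#'   rotation is not modelled).
#' @param dr_cap Prescribed dose-rate cap for the segment *ending* at this
#'   control point, as a fraction of the maximum dose rate (`NA` leaves the
#'   controller free to pick the highest feasible bin).
#' @return A one-row tibble with columns `cum_mu`, `gantry`, `a01..a40`,
#'   `b01..b40`, `jaw_l`, `jaw_r`, `coll`, `dr_cap`.
#' @export
control_point <- function(cum_mu, gantry = 0, a = -0.25, b = 0.25,
                          jaw_l = NULL, jaw_r = NULL, coll = 0,
                          dr_cap = NA_real_) {
  a <- rep_len(a, N_PAIRS)
  b <- rep_len(b, N_PAIRS)
  if (is.null(jaw_l)) jaw_l <- min(a)
  if (is.null(jaw_r)) jaw_r <- max(b)
  row <- c(
    list(cum_mu = cum_mu, gantry = gantry),
    stats::setNames(as.list(a), leaf_bank_cols("a")),
    stats::setNames(as.list(b), leaf_bank_cols("b")),
    list(jaw_l = jaw_l, jaw_r = jaw_r, coll = coll, dr_cap = dr_cap)
  )
  tibble::as_tibble(row)
}

#' Assemble a VMAT plan
#'
#' @param name Plan name.
#' @param control_points Tibble of control points, one row each (see
#'   [control_point()]); at least two rows, `cum_mu` non-decreasing and
#'   starting at zero.
#' @param energy_label Beam energy label, e.g. `"6 MV"`.
#' @param strip_specs Optional tibble of strip metadata used by the
#'   analysis functions (one row per strip: `index`, `x_start`, `x_end`,
#'   `dr_factor`, `gs_factor`, `mlc_speed_factor`, `planned_mu`,
#'   `traversal_count`, `arc_span`).
#' @param meta Optional named list of extra generator metadata (picket
#'   layout, junction/turn records, gaps).
#' @param notes Free-text notes.
#' @return An object of class `vmat_plan`.
#' @export
vmat_plan <- function(name, control_points, energy_label = "6 MV",
                      strip_specs = NULL, meta = list(), notes = "") {
  cps <- tibble::as_tibble(control_points)
  need <- c("cum_mu", "gantry", leaf_bank_cols("a"), leaf_bank_cols("b"),
            "jaw_l", "jaw_r", "coll")
  missing <- setdiff(need, names(cps))
  if (length(missing) > 0) {
    stop("control points lack columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"dr_cap" %in% names(cps)) cps$dr_cap <- NA_real_
  cps$dr_cap <- as.numeric(cps$dr_cap)
  if (nrow(cps) < 2) stop("a plan needs at least 2 control points", call. = FALSE)
  if (abs(cps$cum_mu[1]) > 1e-9) {
    stop("first control point must have cum_mu = 0", call. = FALSE)
  }
  if (any(diff(cps$cum_mu) < -1e-9)) {
    stop("cum_mu must be non-decreasing", call. = FALSE)
  }
  structure(
    list(
      name = name, energy_label = energy_label,
      control_points = cps,
      strip_specs = strip_specs, meta = meta, notes = notes
    ),
    class = "vmat_plan"
  )
}

#' @export
print.vmat_plan <- function(x, ...) {
  cps <- x$control_points
  cat(sprintf(
    "<vmat_plan> %s (%s): %d control points, %.1f MU, gantry %g to %g deg\n",
    x$name, x$energy_label, nrow(cps), max(cps$cum_mu),
    cps$gantry[1], cps$gantry[nrow(cps)]
  ))
  if (!is.null(x$strip_specs)) {
    cat(sprintf("  %d strips\n", nrow(x$strip_specs)))
  }
  invisible(x)
}

#' Summarise a plan in one row
#'
#' @param x A `vmat_plan`.
#' @param ... Unused.
#' @return A one-row tibble: control point count, total MU, arc span,
#'   total largest-leaf travel and strip count.
#' @method glance vmat_plan
#' @export
glance.vmat_plan <- function(x, ...) {
  segs <- plan_segments(x)
  tibble::tibble(
    name = x$name,
    n_control_points = nrow(x$control_points),
    total_mu = max(x$control_points$cum_mu),
    arc_span = sum(segs$d_theta),
    total_leaf_travel = sum(segs$max_leaf_travel),
    n_strips = if (is.null(x$strip_specs)) 0L else nrow(x$strip_specs)
  )
}

#' Per-segment kinematics of a plan
#'
#' @param plan A `vmat_plan`.
#' @return A tibble with one row per segment: `segment`, `d_mu`, `d_theta`,
#'   `max_leaf_travel`, `jaw_travel`, `dr_cap`.
#' @export
plan_segments <- function(plan) {
  cps <- plan$control_points
  n <- nrow(cps)
  purrr::map_dfr(seq_len(n - 1L), function(i) {
    seg <- segment_kinematics(cps[i, ], cps[i + 1L, ])
    tibble::tibble(
      segment = i,
      d_mu = seg$d_mu, d_theta = seg$d_theta,
      max_leaf_travel = seg$max_leaf_travel, jaw_travel = seg$jaw_travel,
      dr_cap = seg$dr_cap
    )
  })
}

# a leaf pair is treated as parked when it is closed and driven to the
# extreme of the travel range (out from under the open field)
pair_is_parked <- function(a, b) {
  (b - a) < 1e-6 & (a <= -(LEAF_POS_MAX - 1) | a >= (LEAF_POS_MAX - 1))
}

#' Validate a plan against machine limits
#'
#' Checks every control point and segment of a plan for physical
#' deliverability: leaf-pair gaps below the minimum (parked pairs exempt),
#' leaf and jaw positions out of the travel range, decreasing cumulative
#' MU, and arc segments below the controller's MU-per-degree floor. The
#' floor check allows for MU-entry quantisation: a segment whose planned MU
#' sits within half an MU-resolution step of the floor is not flagged.
#'
#' Violations are data, not errors: an empty tibble means deliverable.
#' Deliberately over-maximum strips (planned dose rate or gantry speed 1.2x
#' the limit) validate clean here; the simulator caps them at run time.
#'
#' @param plan A `vmat_plan`.
#' @param limits A [machine_limits()] object.
#' @return A tibble of violation records: `type`, `where` (control point or
#'   segment index), `pair` (leaf pair, if relevant), `value`, `limit`,
#'   `message`.
#' @export
validate_plan <- function(plan, limits = machine_limits()) {
  cps <- plan$control_points
  la <- leaf_bank_cols("a")
  lb <- leaf_bank_cols("b")
  A <- as.matrix(cps[, la])
  B <- as.matrix(cps[, lb])
  out <- list()
  rec <- function(type, where, pair, value, limit, message) {
    tibble::tibble(
      type = type, where = as.integer(where), pair = as.integer(pair),
      value = value, limit = limit, message = message
    )
  }

  # gap check
  gap <- B - A
  parked <- pair_is_parked(A, B)
  bad <- which(gap < limits$min_gap - 1e-9 & !parked, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    out <- c(out, list(rec(
      "min_gap", bad[, 1], bad[, 2], gap[bad], limits$min_gap,
      sprintf(
        "leaf pair %d gap %.3f cm below minimum at control point %d",
        bad[, 2], gap[bad], bad[, 1]
      )
    )))
  }

  # travel range
  pos_bad <- which(abs(A) > LEAF_POS_MAX + 1e-9 | abs(B) > LEAF_POS_MAX + 1e-9,
    arr.ind = TRUE
  )
  if (nrow(pos_bad) > 0) {
    out <- c(out, list(rec(
      "leaf_range", pos_bad[, 1], pos_bad[, 2], NA_real_, LEAF_POS_MAX,
      sprintf(
        "leaf pair %d out of travel range at control point %d",
        pos_bad[, 2], pos_bad[, 1]
      )
    )))
  }

  # monotone MU
  dmu <- diff(cps$cum_mu)
  dec <- which(dmu < -1e-9)
  if (length(dec) > 0) {
    out <- c(out, list(rec(
      "mu_decreasing", dec, NA, dmu[dec], 0,
      sprintf("cumulative MU decreases across segment %d", dec)
    )))
  }

  # MU-per-degree floor on arc segments, with quantisation allowance
  segs <- plan_segments(plan)
  arc <- segs[segs$d_theta > 1e-9, ]
  if (nrow(arc) > 0) {
    ratio <- arc$d_mu / arc$d_theta
    slack <- (limits$mu_resolution / 2) / arc$d_theta
    low <- which(ratio < limits$mu_per_degree_min - slack - 1e-12)
    if (length(low) > 0) {
      out <- c(out, list(rec(
        "mu_per_degree", arc$segment[low], NA, ratio[low],
        limits$mu_per_degree_min,
        sprintf(
          "segment %d delivers %.4f MU/deg, below the %.2f MU/deg floor",
          arc$segment[low], ratio[low], limits$mu_per_degree_min
        )
      )))
    }
  }

  if (length(out) == 0) {
    return(tibble::tibble(
      type = character(), where = integer(), pair = integer(),
      value = numeric(), limit = numeric(), message = character()
    ))
  }
  dplyr::bind_rows(out)
}
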