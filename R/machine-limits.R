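#' Machine limits for an Elekta-style VMAT delivery system
#'
#' Bundles the nominal maxima and physical constraints of the delivery
#' system: maximum dose rate, axis speed limits (MLC leaves, backup jaws,
#' gantry), the number of binary dose-rate bins, the minimum leaf-pair gap,
#' the MU-per-degree floor the controller enforces on arc segments, the MU
#' entry resolution, the dose-rate switching time and the gantry inertia
#' compensation distance (exposed as a parameter only, zero by default).
#'
#' Defaults are the nominal values of an Elekta Infinity with the MLCi2
#' head: 600 MU/min maximum dose rate in six halving bins, 2 cm/s leaves,
#' 1.5 cm/s backup jaws, 6 deg/s gantry, 0.5 cm minimum gap at isocenter
#' and a 0.1 MU/deg floor.
#'
#' @param dr_max Maximum dose rate, MU/min.
#' @param mlc_speed_max Maximum MLC leaf speed, cm/s at the isocenter plane.
#' @param jaw_speed_max Maximum backup-jaw speed, cm/s at the isocenter plane.
#' @param gantry_speed_max Maximum gantry speed, degrees/s.
#' @param n_dr_bins Number of dose-rate bins; bin `k` runs at `dr_max / 2^k`.
#' @param min_gap Minimum open leaf-pair gap, cm at isocenter.
#' @param mu_per_degree_min Controller floor on MU delivered per degree of
#'   gantry rotation, MU/degree.
#' @param mu_resolution Smallest enterable MU increment, MU.
#' @param dr_switch_time Time for the controller to settle on a new
#'   dose-rate bin, seconds.
#' @param gantry_inertia_distance Gantry ramp-up dead band, degrees.
#'
#' @return An object of class `machine_limits` (a named list).
#' @examples
#' lim <- machine_limits()
#' lim$dr_max
#' @export
machine_limits <- function(dr_max = 600,
                           mlc_speed_max = 2,
                           jaw_speed_max = 1.5,
                           gantry_speed_max = 6,
                           n_dr_bins = 6,
                           min_gap = 0.5,
                           mu_per_degree_min = 0.1,
                           mu_resolution = 0.1,
                           dr_switch_time = 0.25,
                           gantry_inertia_distance = 0) {
  lim <- list(
    dr_max = dr_max,
    mlc_speed_max = mlc_speed_max,
    jaw_speed_max = jaw_speed_max,
    gantry_speed_max = gantry_speed_max,
    n_dr_bins = as.integer(n_dr_bins),
    min_gap = min_gap,
    mu_per_degree_min = mu_per_degree_min,
    mu_resolution = mu_resolution,
    dr_switch_time = dr_switch_time,
    gantry_inertia_distance = gantry_inertia_distance
  )
  num <- vapply(lim, is.numeric, logical(1))
  if (!all(num)) {
    stop("all machine limit fields must be numeric", call. = FALSE)
  }
  pos <- c(
    "dr_max", "mlc_speed_max", "jaw_speed_max", "gantry_speed_max",
    "min_gap", "mu_per_degree_min", "mu_resolution"
  )
  bad <- pos[vapply(pos, function(f) lim[[f]] <= 0, logical(1))]
  if (length(bad) > 0) {
    stop("machine limit fields must be positive: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (lim$n_dr_bins < 1L) stop("n_dr_bins must be >= 1", call. = FALSE)
  if (lim$mu_resolution > 1) stop("mu_resolution must be <= 1 MU", call. = FALSE)
  if (lim$dr_switch_time < 0 || lim$gantry_inertia_distance < 0) {
    stop("dr_switch_time and gantry_inertia_distance must be >= 0", call. = FALSE)
  }
  structure(lim, class = "machine_limits")
}

#' @export
print.machine_limits <- function(x, ...) {
  cat("<machine_limits>\n")
  cat(sprintf("  dose rate      : %g MU/min in %d halving bins\n", x$dr_max, x$n_dr_bins))
  cat(sprintf("  MLC / jaw speed: %g / %g cm/s\n", x$mlc_speed_max, x$jaw_speed_max))
  cat(sprintf("  gantry speed   : %g deg/s\n", x$gantry_speed_max))
  cat(sprintf(
    "  min gap %g cm, floor %g MU/deg, MU step %g, DR switch %g s\n",
    x$min_gap, x$mu_per_degree_min, x$mu_resolution, x$dr_switch_time
  ))
  invisible(x)
}

# dose rates are stored in MU/min everywhere user-facing; internal kinematics
# work in MU/s
mu_per_min_to_s <- function(dr) dr / 60

#' Round half away from zero
#'
#' `round()` in R rounds half to even; dose-rate bin labels and MU
#' quantisation follow the conventional half-up rule instead (18.75 MU/min
#' is labelled 19, not 18).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return `x` rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Quantize MU values to the machine's entry resolution
#'
#' @param mu Numeric MU values.
#' @param resolution Smallest enterable MU increment (default 0.1 MU).
#' @return `mu` rounded (half up) to a multiple of `resolution`.
#' @export
quantize_mu <- function(mu, resolution = 0.1) {
  round_half_up(mu / resolution) * resolution
}

#' Build the dose-rate bin table
#'
#' Elekta-style controllers run at discrete dose rates, each half the
#' previous one, counting down from the machine maximum. The exact bin `k`
#' (0-based) is `dr_max / 2^k`; the nominal bin is the exact value rounded
#' (half up) to an integer MU/min, the form entered into a treatment
#' planning system.
#'
#' @param dr_max Maximum dose rate, MU/min.
#' @param n_bins Number of bins (>= 1).
#' @return A tibble of class `dose_rate_bin_table` with columns `bin`
#'   (0-based index), `exact` (MU/min) and `nominal` (integer MU/min).
#' @examples
#' build_bin_table(600, 6)$nominal # 600 300 150 75 38 19
#' @export
build_bin_table <- function(dr_max, n_bins) {
  if (!is.numeric(dr_max) || length(dr_max) != 1 || dr_max <= 0) {
    stop("dr_max must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 1) {
    stop("n_bins must be a single integer >= 1", call. = FALSE)
  }
  k <- seq_len(as.integer(n_bins)) - 1L
  exact <- dr_max / 2^k
  tbl <- tibble::tibble(
    bin = k,
    exact = exact,
    nominal = as.integer(round_half_up(exact))
  )
  class(tbl) <- c("dose_rate_bin_table", class(tbl))
  tbl
}

#' Kinematics of one control-point segment
#'
#' Differences the machine state between two consecutive control points of
#' a plan: delivered MU, gantry rotation, the largest per-leaf travel over
#' all 80 leaves, and the larger of the two backup-jaw travels.
#'
#' @param cp_i,cp_j Consecutive one-row control-point tibbles (see
#'   [control_point()]).
#' @return An object of class `segment_kinematics`: a list with fields
#'   `d_mu` (MU), `d_theta` (degrees), `max_leaf_travel` (cm), `jaw_travel`
#'   (cm) and `dr_cap` (prescribed dose-rate cap as a fraction of the
#'   maximum for the segment, `NA` when the controller is free to choose).
#' @examples
#' cps <- gen_speed_limit_test("mlc", 10)$control_points
#' segment_kinematics(cps[1, ], cps[2, ])
#' @export
segment_kinematics <- function(cp_i, cp_j) {
  d_mu <- cp_j$cum_mu - cp_i$cum_mu
  if (d_mu < -1e-9) {
    stop("cumulative MU decreases across the segment: corrupt plan", call. = FALSE)
  }
  la <- leaf_bank_cols("a")
  lb <- leaf_bank_cols("b")
  travel_a <- abs(as.numeric(cp_j[1, la]) - as.numeric(cp_i[1, la]))
  travel_b <- abs(as.numeric(cp_j[1, lb]) - as.numeric(cp_i[1, lb]))
  seg <- list(
    d_mu = max(d_mu, 0),
    d_theta = abs(cp_j$gantry - cp_i$gantry),
    max_leaf_travel = max(travel_a, travel_b),
    jaw_travel = max(
      abs(cp_j$jaw_l - cp_i$jaw_l),
      abs(cp_j$jaw_r - cp_i$jaw_r)
    ),
    dr_cap = if ("dr_cap" %in% names(cp_j)) cp_j$dr_cap else NA_real_
  )
  structure(seg, class = "segment_kinematics")
}

#' Time to deliver a segment at a given dose rate
#'
#' @param seg A `segment_kinematics` object.
#' @param dr Dose rate in MU/min.
#' @return Duration in seconds.
#' @export
segment_duration <- function(seg, dr) {
  seg$d_mu / mu_per_min_to_s(dr)
}

#' Select the dose-rate bin for a segment
#'
#' Models the controller's bin-selection rule: the highest dose rate (the
#' smallest bin index) at which every axis can keep up. At dose rate `R`
#' (MU/s) a segment of `d_mu` MU takes `d_mu / R` seconds, so an axis with
#' travel `d` must move at `d * R / d_mu`; the selected bin is the smallest
#' `k` for which every such speed is within its limit. Generated test plans
#' may additionally prescribe a dose-rate cap for a segment (the way custom
#' acceptance-test files drive a strip at a chosen bin); bins above the cap
#' are then not considered.
#'
#' If even the lowest bin over-speeds some axis, that bin is returned with
#' `capped = TRUE`; the simulator then runs the axis at its maximum and
#' extends the segment time, conserving MU.
#'
#' @param seg A `segment_kinematics` object with `d_mu > 0`.
#' @param limits A [machine_limits()] object.
#' @param dr_cap Optional dose-rate cap as a fraction of `dr_max`
#'   (overrides `seg$dr_cap`); `NA` or `Inf` leaves the controller free.
#' @return A list with `bin` (0-based index), `limiting_axis` (one of
#'   `"mlc"`, `"jaw"`, `"gantry"`, `"none"` -- the axis that forbids bin
#'   `k - 1`), and `capped` (`TRUE` when no bin is feasible).
#' @examples
#' lim <- machine_limits()
#' seg <- list(d_mu = 50, d_theta = 0, max_leaf_travel = 10, jaw_travel = 0,
#'             dr_cap = NA)
#' class(seg) <- "segment_kinematics"
#' select_bin(seg, lim) # bin 0: 10 cm in 5 s is exactly 2 cm/s
#' @export
select_bin <- function(seg, limits, dr_cap = NULL) {
  if (is.null(dr_cap)) dr_cap <- seg$dr_cap
  if (is.null(dr_cap) || is.na(dr_cap)) dr_cap <- Inf
  if (seg$d_mu <= 0) {
    if (seg$max_leaf_travel > 0 || seg$jaw_travel > 0 || seg$d_theta > 0) {
      stop("segment with zero MU but nonzero travel: instantaneous motion",
        call. = FALSE
      )
    }
    return(list(bin = 0L, limiting_axis = "none", capped = FALSE))
  }
  bins <- build_bin_table(limits$dr_max, limits$n_dr_bins)
  allowed <- which(bins$exact <= dr_cap * limits$dr_max * (1 + 1e-12))
  if (length(allowed) == 0) allowed <- nrow(bins) # cap below lowest bin
  rel_tol <- 1 + 1e-9

  over_axis <- function(k) {
    rate <- mu_per_min_to_s(bins$exact[k + 1L]) # MU/s
    speeds <- c(
      mlc = seg$max_leaf_travel * rate / seg$d_mu,
      jaw = seg$jaw_travel * rate / seg$d_mu,
      gantry = seg$d_theta * rate / seg$d_mu
    )
    maxima <- c(
      mlc = limits$mlc_speed_max,
      jaw = limits$jaw_speed_max,
      gantry = limits$gantry_speed_max
    )
    excess <- speeds / maxima
    if (all(excess <= rel_tol)) {
      return(NA_character_)
    }
    names(which.max(excess))
  }

  k_min <- min(allowed) - 1L # 0-based smallest allowed bin
  for (k in (min(allowed):max(allowed)) - 1L) {
    ax <- over_axis(k)
    if (is.na(ax)) {
      limiting <- if (k == k_min) "none" else over_axis(k - 1L)
      if (is.na(limiting)) limiting <- "none"
      return(list(bin = as.integer(k), limiting_axis = limiting, capped = FALSE))
    }
  }
  # nothing feasible: lowest allowed bin, flagged; simulator caps axis speeds
  k <- max(allowed) - 1L
  list(bin = as.integer(k), limiting_axis = over_axis(k), capped = TRUE)
}

#' Recover a maximum axis speed from a bin-transition MU threshold
#'
#' The internal-consistency speed tests deliver a fixed travel and search
#' for the smallest MU that still runs at the top dose-rate bin. At that
#' threshold the axis moves at exactly its maximum speed, so the maximum
#' can be recovered as `speed = dr_max * travel / mu_threshold` with
#' `dr_max` converted to MU/s.
#'
#' @param mu_threshold Smallest MU still delivered at the top bin, MU.
#' @param travel Axis travel, cm (leaves, jaws) or degrees (gantry).
#' @param dr_max Maximum dose rate, MU/min.
#' @return The implied maximum axis speed, in `travel` units per second.
#' @examples
#' invert_max_speed(50, 10, 600) # 2 cm/s
#' invert_max_speed(300, 180, 600) # 6 deg/s
#' @export
invert_max_speed <- function(mu_threshold, travel, dr_max) {
  if (any(c(mu_threshold, travel, dr_max) <= 0)) {
    stop("mu_threshold, travel and dr_max must all be positive", call. = FALSE)
  }
  mu_per_min_to_s(dr_max) * travel / mu_threshold
}
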