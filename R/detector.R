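#' Detector models
#'
#' Describes the measurement surface fluence is rendered onto: an EPID
#' panel (fine pixel grid, default 0.256 mm projected pitch at 100 cm SAD,
#' with a small optical blur) or a gantry-mounted 2D diode array (coarse
#' grid at the diode spacing, default 1 cm). The cross-plane axis `x` is
#' the leaf travel direction.
#'
#' @param kind `"epid"` or `"diode_array"`.
#' @param pixel_pitch EPID pixel pitch, mm at 100 cm SAD.
#' @param extent Detector extent, cm, as `c(x, y)`; defaults to 28 cm
#'   (EPID) or 32 cm (diode array).
#' @param diode_spacing Diode spacing, cm (diode array only).
#' @param blur_sigma Gaussian blur sigma, mm (ideal-optics point spread;
#'   default 0.5 mm for the EPID, 0 for the diode array).
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(kind = c("epid", "diode_array"),
                           pixel_pitch = 0.256, extent = NULL,
                           diode_spacing = 1.0, blur_sigma = NULL) {
  kind <- match.arg(kind)
  if (is.null(extent)) extent <- if (kind == "epid") c(28, 28) else c(32, 32)
  if (is.null(blur_sigma)) blur_sigma <- if (kind == "epid") 0.5 else 0
  if (pixel_pitch <= 0 || diode_spacing <= 0) {
    stop("pixel pitch and diode spacing must be positive", call. = FALSE)
  }
  structure(
    list(
      kind = kind, pixel_pitch = pixel_pitch, extent = extent,
      diode_spacing = diode_spacing, blur_sigma = blur_sigma
    ),
    class = "detector_model"
  )
}

detector_pitch_cm <- function(detector) {
  if (detector$kind == "epid") detector$pixel_pitch / 10 else detector$diode_spacing
}

new_fluence_image <- function(values, x, y, meta = list()) {
  stopifnot(nrow(values) == length(y), ncol(values) == length(x))
  structure(list(values = values, x = x, y = y, meta = meta),
    class = "fluence_image"
  )
}

#' @export
print.fluence_image <- function(x, ...) {
  cat(sprintf(
    "<fluence_image> %d x %d px, x [%.2f, %.2f] cm, y [%.2f, %.2f] cm, max %.3f\n",
    length(x$y), length(x$x), min(x$x), max(x$x), min(x$y), max(x$y),
    max(x$values)
  ))
  invisible(x)
}

gaussian_blur_1d <- function(v, sigma_px) {
  if (sigma_px <= 0) {
    return(v)
  }
  hw <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-hw:hw, sd = sigma_px)
  k <- k / sum(k)
  n <- length(v)
  padded <- c(rep(v[1], hw), v, rep(v[n], hw))
  as.numeric(stats::filter(padded, k, sides = 2))[hw + seq_len(n)]
}

# accumulate MU-weighted open time onto a 1-D pixel grid for one leaf pair
accumulate_pair <- function(a, b, jaw_l, jaw_r, dmu, x_edges) {
  nx <- length(x_edges) - 1L
  pitch <- x_edges[2] - x_edges[1]
  prof <- numeric(nx)
  lo <- pmax(a, jaw_l)
  hi <- pmin(b, jaw_r)
  ok <- which(hi > lo & dmu > 0)
  for (k in ok) {
    l <- lo[k]
    h <- hi[k]
    if (h <= x_edges[1] || l >= x_edges[nx + 1L]) next
    l <- max(l, x_edges[1])
    h <- min(h, x_edges[nx + 1L])
    i0 <- findInterval(l, x_edges, rightmost.closed = TRUE)
    i1 <- findInterval(h, x_edges, rightmost.closed = TRUE)
    i1 <- min(i1, nx)
    if (i0 == i1) {
      prof[i0] <- prof[i0] + dmu[k] * (h - l) / pitch
    } else {
      prof[i0] <- prof[i0] + dmu[k] * (x_edges[i0 + 1L] - l) / pitch
      prof[i1] <- prof[i1] + dmu[k] * (h - x_edges[i1]) / pitch
      if (i1 - i0 > 1L) {
        idx <- (i0 + 1L):(i1 - 1L)
        prof[idx] <- prof[idx] + dmu[k]
      }
    }
  }
  prof
}

#' Render fluence from a delivery trace onto a detector
#'
#' Integrates `DR(t) * open(pixel, t)` over the trace with ideal binary
#' apertures (leaves and backup jaws), i.e. each pixel accumulates the MU
#' delivered while it is uncovered, with sub-pixel aperture edges handled
#' by fractional coverage. An optional Gaussian blur models the detector
#' point spread; multiplicative noise and vertical pixilation lines from
#' the error model are applied last, under the given seed. With zero noise
#' and no lines the render is deterministic. Fluence units are MU-weighted
#' open time (relative units).
#'
#' @param trace A `delivery_trace` from [simulate_delivery()].
#' @param detector A [detector_model()].
#' @param errors An [error_model()] (for noise/pixilation; geometric errors
#'   act during simulation). Defaults to the trace's own error model.
#' @param seed Integer seed for the stochastic render components.
#' @return A `fluence_image`.
#' @examples
#' tr <- simulate_delivery(gen_utility_fields("open_field", mu = 100))
#' img <- render_fluence(tr, detector_model("diode_array"))
#' max(img$values) # 100 MU open time
#' @export
render_fluence <- function(trace, detector = detector_model(),
                           errors = NULL, seed = 1L) {
  if (is.null(errors)) errors <- trace$errors
  pitch <- detector_pitch_cm(detector)
  half_x <- detector$extent[1] / 2
  half_y <- detector$extent[2] / 2
  nx <- floor(detector$extent[1] / pitch)
  ny <- floor(detector$extent[2] / pitch)
  x_edges <- -half_x + pitch * (0:nx)
  x_centers <- x_edges[-1] - pitch / 2
  y_edges <- -half_y + pitch * (0:ny)
  y_centers <- y_edges[-1] - pitch / 2

  s <- trace$samples
  n <- nrow(s)
  dmu <- diff(s$cum_mu)
  mid <- function(v) (v[-1] + v[-n]) / 2
  jl <- mid(s$jaw_l)
  jr <- mid(s$jaw_r)

  A <- trace$bank_a
  B <- trace$bank_b

  # open-aperture extent check (parked pairs are closed and irrelevant)
  open_any <- B - A > 1e-6
  if (any(open_any)) {
    x_need <- range(
      pmax(A[open_any], min(s$jaw_l)), pmin(B[open_any], max(s$jaw_r))
    )
    if (x_need[1] < -half_x - 1e-9 || x_need[2] > half_x + 1e-9) {
      warning("detector does not cover the open field; render cropped")
    }
  }
  traj <- lapply(seq_len(N_PAIRS), function(j) c(A[, j], B[, j]))
  first_of_group <- !duplicated(traj)
  group_of <- match(traj, traj[first_of_group])
  profiles <- vector("list", sum(first_of_group))
  sigma_px <- detector$blur_sigma / (pitch * 10)
  for (g in seq_along(profiles)) {
    j <- which(group_of == g)[1]
    a_mid <- mid(A[, j])
    b_mid <- mid(B[, j])
    p <- accumulate_pair(a_mid, b_mid, jl, jr, dmu, x_edges)
    profiles[[g]] <- gaussian_blur_1d(p, sigma_px)
  }

  pair_of_row <- floor(y_centers) + 21L # pair j spans [j - 21, j - 20) cm
  mat <- matrix(0, nrow = ny, ncol = nx)
  for (j in seq_len(N_PAIRS)) {
    rows <- which(pair_of_row == j)
    if (length(rows) > 0) {
      mat[rows, ] <- matrix(profiles[[group_of[j]]],
        nrow = length(rows), ncol = nx, byrow = TRUE
      )
    }
  }

  if (errors$noise_sigma > 0 || !is.null(errors$pixilation_lines)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    if (errors$noise_sigma > 0) {
      mat <- mat * matrix(stats::rnorm(length(mat), 1, errors$noise_sigma),
        nrow = ny
      )
    }
    for (k in seq_len(NROW(errors$pixilation_lines))) {
      ln <- errors$pixilation_lines[k, ]
      col <- as.integer(ln$column)
      if (col >= 1 && col <= nx) mat[, col] <- mat[, col] * (1 + ln$amplitude)
    }
  }

  new_fluence_image(mat, x_centers, y_centers, meta = list(
    plan = trace$plan_name, seed = seed, detector = detector,
    errors = errors, pitch = pitch
  ))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Extract a cross-plane profile from a fluence image
#'
#' Averages image rows over an in-plane band and returns the profile along
#' the leaf-travel axis.
#'
#' @param image A `fluence_image`.
#' @param y_range In-plane band `c(lo, hi)` in cm, or `NULL` for all rows.
#' @param pair Alternatively, a leaf pair index: uses the central 80% of
#'   that pair's 1 cm row.
#' @return A tibble with columns `x` (cm) and `value`.
#' @export
extract_profile <- function(image, y_range = NULL, pair = NULL) {
  if (!is.null(pair)) {
    y_range <- c(pair - 21 + 0.1, pair - 20 - 0.1)
  }
  rows <- if (is.null(y_range)) {
    seq_along(image$y)
  } else {
    which(image$y >= y_range[1] & image$y <= y_range[2])
  }
  if (length(rows) == 0) stop("no image rows in the requested band", call. = FALSE)
  tibble::tibble(
    x = image$x,
    value = colMeans(image$values[rows, , drop = FALSE])
  )
}

#' Sample a fluence image at detector points
#'
#' Nearest-pixel readings for an EPID, or diode-aperture averages (the
#' pixels within half a diode spacing of the point) for a diode array.
#'
#' @param image A `fluence_image`.
#' @param detector A [detector_model()].
#' @param points A data frame/tibble with columns `x` and `y`, cm.
#' @return The `points` tibble with a `reading` column appended.
#' @export
sample_detector <- function(image, detector, points) {
  points <- tibble::as_tibble(points)
  if (any(points$x < min(image$x) | points$x > max(image$x) |
            points$y < min(image$y) | points$y > max(image$y))) {
    stop("sampling point outside the image extent", call. = FALSE)
  }
  read_one <- function(px, py) {
    if (detector$kind == "diode_array") {
      hw <- detector$diode_spacing / 2
      cols <- which(abs(image$x - px) <= hw)
      rows <- which(abs(image$y - py) <= hw)
      mean(image$values[rows, cols, drop = FALSE])
    } else {
      i <- which.min(abs(image$y - py))
      j <- which.min(abs(image$x - px))
      image$values[i, j]
    }
  }
  points$reading <- purrr::map2_dbl(points$x, points$y, read_one)
  points
}
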