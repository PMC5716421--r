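#' Locate picket peaks in a fluence image
#'
#' Pickets are located the way a physicist reads the image: the profile is
#' split into per-picket windows (runs above a prominence threshold) and
#' the peak is the local pixel with the maximum value in each. Ties between
#' equal-valued maxima are flagged and broken toward the smaller
#' cross-plane coordinate, never silently resolved.
#'
#' @param image A `fluence_image`, or a profile tibble with columns `x`
#'   and `value`.
#' @param n_expected Number of pickets the image must contain.
#' @param y_range Optional in-plane band (cm) to average over when `image`
#'   is a `fluence_image`.
#' @return A tibble with one row per picket: `picket`, `x_peak` (cm),
#'   `value`, `tie` (logical).
#' @export
find_picket_peaks <- function(image, n_expected, y_range = NULL) {
  prof <- if (inherits(image, "fluence_image")) {
    extract_profile(image, y_range = y_range)
  } else {
    tibble::as_tibble(image)
  }
  v <- prof$value
  baseline <- stats::median(v[v > 0.05 * max(v)])
  thr <- baseline + 0.3 * (max(v) - baseline)
  above <- v > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- which(runs$values)
  if (length(idx) != n_expected) {
    stop(sprintf(
      "found %d picket candidates, expected %d", length(idx), n_expected
    ), call. = FALSE)
  }
  out <- purrr::map_dfr(seq_along(idx), function(k) {
    sel <- starts[idx[k]]:ends[idx[k]]
    vv <- v[sel]
    peak_val <- max(vv)
    at <- sel[which(vv >= peak_val * (1 - 1e-12))]
    tibble::tibble(
      picket = k,
      x_peak = prof$x[min(at)],
      value = peak_val,
      tie = length(at) > 1L
    )
  })
  out
}

#' Sub-pixel picket metrics from a profile
#'
#' Measures each picket's centre and strip width from the excess fluence
#' above the sweeping-gap baseline. The excess area is blur- and
#' pixelisation-invariant, so with baseline height `h0 = gap * DR / v` and
#' excess-per-length `h = width * DR / v` the strip width follows from
#' `width = sqrt(area * gap / h0)`; the centre is the excess centroid.
#' Both are sub-pixel estimates.
#'
#' @param profile Tibble with `x` (cm, uniform spacing) and `value`.
#' @param windows Tibble with `x_lo`, `x_hi` per picket window.
#' @param gap The plan's sweeping gap, cm.
#' @return Tibble: `picket`, `centre` (cm), `width` (cm), `area`,
#'   `baseline`.
#' @export
picket_metrics <- function(profile, windows, gap) {
  pitch <- stats::median(diff(profile$x))
  purrr::map_dfr(seq_len(nrow(windows)), function(k) {
    sel <- profile$x >= windows$x_lo[k] & profile$x <= windows$x_hi[k]
    x <- profile$x[sel]
    v <- profile$value[sel]
    n <- length(v)
    edge <- unique(c(seq_len(ceiling(n / 4)), (n - ceiling(n / 4) + 1L):n))
    baseline <- stats::median(v[edge])
    excess <- pmax(v - baseline, 0)
    area <- sum(excess) * pitch
    centre <- if (area > 0) sum(x * excess) / sum(excess) else NA_real_
    tibble::tibble(
      picket = k, centre = centre,
      width = sqrt(area * gap / baseline),
      area = area, baseline = baseline
    )
  })
}

#' Per-pair picket measurements from a fence image
#'
#' Extracts one profile per leaf pair whose row intersects the fence field
#' and measures every picket's centre and width with [picket_metrics()].
#'
#' @param image A `fluence_image` of a picket fence.
#' @param plan The generating `vmat_plan` (for the picket layout metadata).
#' @param pairs Leaf pairs to analyse; defaults to all pairs whose rows lie
#'   inside the image and the fence field.
#' @return Tibble: `pair`, `picket`, `nominal` (cm), `centre`, `width`.
#' @export
analyze_picket_image <- function(image, plan, pairs = NULL) {
  pk <- plan$meta$picket_positions
  gap <- plan$meta$gap
  if (is.null(pk)) stop("plan carries no picket metadata", call. = FALSE)
  half_win <- if (length(pk) > 1) min(diff(pk)) / 2 else 1.5
  windows <- tibble::tibble(x_lo = pk - half_win, x_hi = pk + half_win)
  if (is.null(pairs)) {
    n_field <- if (!is.null(plan$meta$field_size)) plan$meta$field_size else 25
    pairs <- pairs_in_field(min(n_field, 2 * max(abs(image$y))))
  }
  purrr::map_dfr(pairs, function(j) {
    prof <- extract_profile(image, pair = j)
    m <- picket_metrics(prof, windows, gap)
    tibble::tibble(
      pair = j, picket = m$picket, nominal = pk[m$picket],
      centre = m$centre, width = m$width
    )
  })
}

#' Aggregate picket peaks over acquisitions
#'
#' Combines the per-acquisition peak positions of a fence measured at
#' several static gantry angles and during an arc: per picket, the range
#' and mean over the static acquisitions and the arc's deviation from the
#' static mean.
#'
#' @param peaks Tibble with columns `acquisition` (label), `kind`
#'   (`"static"` or `"arc"`), `picket` (index) and `position` (cm).
#' @return A `picket_report` tibble: `picket`, `static_range`,
#'   `static_average`, `arc_minus_average` (all cm; arc columns `NA` when
#'   no arc acquisition is present).
#' @examples
#' peaks <- tibble::tibble(
#'   acquisition = rep(c("g0", "g90", "arc"), each = 1),
#'   kind = c("static", "static", "arc"),
#'   picket = 1, position = c(0.06, 0.14, 0.19)
#' )
#' aggregate_pickets(peaks) # static mean 0.10, arc - mean 0.09
#' @export
aggregate_pickets <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  st <- peaks[peaks$kind == "static", ]
  if (length(unique(st$acquisition)) < 2) {
    stop("need at least 2 static acquisitions", call. = FALSE)
  }
  counts <- dplyr::count(peaks, .data$acquisition)
  if (length(unique(counts$n)) != 1) {
    stop("acquisitions report different picket counts", call. = FALSE)
  }
  static_sum <- st |>
    dplyr::group_by(.data$picket) |>
    dplyr::summarise(
      static_range = max(.data$position) - min(.data$position),
      static_average = mean(.data$position),
      .groups = "drop"
    )
  arc <- peaks[peaks$kind == "arc", ]
  if (nrow(arc) > 0) {
    arc_sum <- arc |>
      dplyr::group_by(.data$picket) |>
      dplyr::summarise(arc_position = mean(.data$position), .groups = "drop")
    static_sum <- dplyr::left_join(static_sum, arc_sum, by = "picket") |>
      dplyr::mutate(arc_minus_average = .data$arc_position - .data$static_average)
  } else {
    static_sum$arc_position <- NA_real_
    static_sum$arc_minus_average <- NA_real_
  }
  class(static_sum) <- c("picket_report", class(static_sum))
  static_sum
}

#' Detect intentional picket-fence errors
#'
#' Compares per-pair picket measurements against the programmed nominal
#' layout and flags leaf pairs whose strip width or peak position deviates
#' by at least the tolerance, with the signed magnitude. Position deviation
#' is judged against the per-picket median across pairs, which cancels any
#' systematic rendering offset common to all pairs.
#'
#' @param measurements Per-pair measurements from [analyze_picket_image()].
#' @param plan The generating `vmat_plan` (for nominal picket width).
#' @param tol Flagging tolerance, cm (default 0.05 = 0.5 mm).
#' @return Tibble of flags: `pair`, `type` (`"width"` or `"shift"`),
#'   `magnitude` (signed deviation, cm), `measured` (cm: mean measured
#'   width, or mean position deviation).
#' @export
detect_picket_errors <- function(measurements, plan, tol = 0.05) {
  nominal_w <- plan$meta$picket_width
  m <- measurements |>
    dplyr::group_by(.data$picket) |>
    dplyr::mutate(pos_dev = .data$centre - .data$nominal -
      stats::median(.data$centre - .data$nominal)) |>
    dplyr::ungroup()
  per_pair <- m |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      width = mean(.data$width),
      shift = mean(.data$pos_dev),
      .groups = "drop"
    )
  flags <- list()
  wd <- per_pair[abs(per_pair$width - nominal_w) >= tol - 1e-9, ]
  if (nrow(wd) > 0) {
    flags <- c(flags, list(tibble::tibble(
      pair = wd$pair, type = "width",
      magnitude = wd$width - nominal_w, measured = wd$width
    )))
  }
  sh <- per_pair[abs(per_pair$shift) >= tol - 1e-9, ]
  if (nrow(sh) > 0) {
    flags <- c(flags, list(tibble::tibble(
      pair = sh$pair, type = "shift",
      magnitude = sh$shift, measured = sh$shift
    )))
  }
  if (length(flags) == 0) {
    return(tibble::tibble(
      pair = integer(), type = character(),
      magnitude = numeric(), measured = numeric()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(flags), .data$pair)
}
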