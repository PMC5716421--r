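#' Centred moving average with truncated edges
#'
#' The n-sample centred moving average used to smooth EPID profiles before
#' reading strip doses and junction excursions (7 pixels = 1.8 mm at the
#' default pitch; 3 pixels = 0.77 mm). Edge samples use the truncated
#' window. The physical window width `n * spacing` is attached as the
#' `window_mm` attribute when the sample spacing is given.
#'
#' @param x Numeric profile values (ordered, uniform spacing), or a tibble
#'   with columns `x` and `value`.
#' @param n Odd window length in samples.
#' @param spacing Sample spacing in mm (optional; used only to report the
#'   window width).
#' @return Smoothed values (or tibble), with attribute `window_mm`.
#' @examples
#' attr(moving_average(rep(1, 50), 7, spacing = 0.256), "window_mm") # 1.792
#' @export
moving_average <- function(x, n, spacing = NULL) {
  if (n %% 2 == 0) stop("the window length n must be odd", call. = FALSE)
  tab <- NULL
  if (is.data.frame(x)) {
    tab <- x
    x <- x$value
  }
  if (n == 1) {
    out <- x
  } else {
    h <- (n - 1L) / 2L
    cs <- cumsum(c(0, x))
    m <- length(x)
    lo <- pmax(seq_len(m) - h, 1L)
    hi <- pmin(seq_len(m) + h, m)
    out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  if (!is.null(tab)) {
    tab$value <- out
    out <- tab
  }
  if (!is.null(spacing)) attr(out, "window_mm") <- n * spacing
  attr(out, "window_samples") <- n
  out
}

#' Remove pixilation spikes from a duplicate pair of profiles
#'
#' Detector pixilation shows as single-column excursions. A sample is
#' declared spiked when it deviates by more than the threshold, in the
#' same direction, from both of its neighbours half a window away in its
#' own profile; the output at each position is the mean of the surviving
#' values from the two repeated acquisitions. Positions spiked in both
#' profiles are returned as missing.
#'
#' @param profile_a,profile_b Equal-length aligned numeric profiles, or
#'   tibbles with `x` and `value`.
#' @param threshold Relative excursion threshold (default 0.03).
#' @param window Neighbour distance, mm (default 0.5).
#' @param spacing Sample spacing, mm (default 0.256); ignored when the
#'   profiles are tibbles with an `x` column in cm.
#' @return A tibble with `x` (index or cm), `value` (cleaned average, `NA`
#'   where both were spiked) and `n_used`.
#' @export
despike_pair <- function(profile_a, profile_b, threshold = 0.03,
                         window = 0.5, spacing = 0.256) {
  get_vals <- function(p) if (is.data.frame(p)) p$value else p
  a <- get_vals(profile_a)
  b <- get_vals(profile_b)
  if (length(a) != length(b)) {
    stop("profiles must be equal length and aligned", call. = FALSE)
  }
  if (is.data.frame(profile_a) && "x" %in% names(profile_a)) {
    xs <- profile_a$x
    spacing <- stats::median(diff(xs)) * 10 # cm -> mm
  } else {
    xs <- seq_along(a)
  }
  k <- max(1L, as.integer(round(window / spacing)))
  spiked <- function(v) {
    m <- length(v)
    left <- v[pmax(seq_len(m) - k, 1L)]
    right <- v[pmin(seq_len(m) + k, m)]
    up <- v > left * (1 + threshold) & v > right * (1 + threshold)
    down <- v < left * (1 - threshold) & v < right * (1 - threshold)
    up | down
  }
  sa <- spiked(a)
  sb <- spiked(b)
  value <- ifelse(sa & sb, NA_real_,
    ifelse(sa, b, ifelse(sb, a, (a + b) / 2))
  )
  tibble::tibble(
    x = xs, value = value,
    n_used = 2L - as.integer(sa) - as.integer(sb)
  )
}

#' Normalize a test image by its open-field reference
#'
#' Pointwise `100 * test / open`, defined only where the open field is
#' above a floor (default 5% of its maximum); pixels below the floor are
#' masked `NA` rather than divided. Both images must share the same pixel
#' geometry; each measurement is meant to be normalized by an open field
#' delivered at the same dose-rate bin.
#'
#' @param test,open_ref `fluence_image`s on identical grids.
#' @param floor Open-field mask threshold as a fraction of its maximum.
#' @return A `fluence_image` in percent of the open field.
#' @export
normalize_to_open <- function(test, open_ref, floor = 0.05) {
  if (!isTRUE(all.equal(test$x, open_ref$x)) ||
        !isTRUE(all.equal(test$y, open_ref$y))) {
    stop("test and open-field images are on different grids", call. = FALSE)
  }
  lim <- floor * max(open_ref$values)
  vals <- 100 * test$values / open_ref$values
  vals[open_ref$values < lim] <- NA_real_
  new_fluence_image(vals, test$x, test$y, meta = c(
    test$meta[setdiff(names(test$meta), "errors")],
    list(normalized_to = open_ref$meta$plan, floor = floor)
  ))
}

#' Per-strip dose statistics
#'
#' Reads the mean and standard deviation of the normalized dose in each
#' strip of a strip test. In diode-array mode, 12 samples at 1 cm spacing
#' across the central 11 cm of the strip length are averaged at the strip
#' midpoint, each at mid-leaf-pair height. In EPID mode the profile is
#' taken over a half-leaf-width (0.5 cm) transverse band centred 0.5 cm
#' superior to the central ray, smoothed with a 7-pixel moving average;
#' the strip value is the smoothed midpoint and the SD is estimated from
#' the raw pixels in the window.
#'
#' @param normalized A normalized `fluence_image` (percent).
#' @param strips Strip metadata (`strip_specs` of the generating plan).
#' @param detector The [detector_model()] the image was rendered on.
#' @param smooth_n EPID smoothing window, pixels (default 7).
#' @param rescale How to set the 100% level: `"median"` (default) scales
#'   the report so the median strip reads 100, reflecting that simulated
#'   fluence is relative (no absolute dosimetry is modelled, so only
#'   strip-to-strip uniformity is meaningful); `"none"` keeps the raw
#'   normalized values.
#' @return A `strip_report` tibble: `index`, factor columns echoed from the
#'   specs, `mean`, `sd`, `n_samples`.
#' @export
strip_stats <- function(normalized, strips, detector, smooth_n = 7,
                        rescale = c("median", "none")) {
  rescale <- match.arg(rescale)
  epid <- detector$kind == "epid"
  res <- purrr::map_dfr(seq_len(nrow(strips)), function(k) {
    mid <- (strips$x_start[k] + strips$x_end[k]) / 2
    if (epid) {
      prof <- extract_profile(normalized, y_range = c(0.25, 0.75))
      prof <- prof[!is.na(prof$value), ] # drop pixels masked at normalization
      sm <- moving_average(prof$value, smooth_n)
      j <- which.min(abs(prof$x - mid))
      win <- max(1L, j - (smooth_n - 1L) %/% 2L):min(length(sm), j + (smooth_n - 1L) %/% 2L)
      tibble::tibble(
        index = strips$index[k], mean = sm[j],
        sd = stats::sd(prof$value[win]), n_samples = length(win)
      )
    } else {
      pts <- tibble::tibble(x = mid, y = seq(-5.5, 5.5, by = 1))
      rd <- sample_detector(normalized, detector, pts)$reading
      rd <- rd[!is.na(rd)]
      if (length(rd) < 12) {
        warning(sprintf(
          "strip %d: only %d of 12 sample sites usable", strips$index[k],
          length(rd)
        ))
      }
      tibble::tibble(
        index = strips$index[k], mean = mean(rd), sd = stats::sd(rd),
        n_samples = length(rd)
      )
    }
  })
  if (rescale == "median") {
    f <- 100 / stats::median(res$mean)
    res$mean <- res$mean * f
    res$sd <- res$sd * f
  }
  out <- dplyr::left_join(
    res,
    strips[, intersect(
      c("index", "dr_factor", "gs_factor", "mlc_speed_factor", "planned_mu"),
      names(strips)
    )],
    by = "index"
  )
  class(out) <- c("strip_report", class(out))
  out
}

#' Compare profiles across dose-rate bins
#'
#' Computes, for each dose-rate bin's open-field profile, the maximum
#' absolute deviation from the reference bin over the central 80% of the
#' field, together with IEC-style flatness (`100 (max - min) / (max +
#' min)`) and symmetry (largest point-vs-mirror difference) over the same
#' region.
#'
#' @param profiles Named list of profile tibbles (`x`, `value`), one per
#'   bin; names are bin labels.
#' @param reference Name of the reference profile (default the first).
#' @return Tibble: `bin`, `max_dev_pct`, `flatness_pct`, `symmetry_pct`.
#' @export
profile_dr_compare <- function(profiles, reference = names(profiles)[1]) {
  ref <- profiles[[reference]]
  open <- which(ref$value > 0.5 * max(ref$value))
  width <- ref$x[max(open)] - ref$x[min(open)]
  centre <- (ref$x[max(open)] + ref$x[min(open)]) / 2
  central <- which(abs(ref$x - centre) <= 0.4 * width)
  purrr::map_dfr(names(profiles), function(nm) {
    p <- profiles[[nm]]
    if (!isTRUE(all.equal(p$x, ref$x))) {
      stop("profiles are not aligned", call. = FALSE)
    }
    rel <- p$value[central] / ref$value[central]
    v <- p$value[central]
    mirrored <- rev(v)
    tibble::tibble(
      bin = nm,
      max_dev_pct = 100 * max(abs(rel - 1)),
      flatness_pct = 100 * (max(v) - min(v)) / (max(v) + min(v)),
      symmetry_pct = 100 * max(abs(v - mirrored) / ((v + mirrored) / 2))
    )
  })
}
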