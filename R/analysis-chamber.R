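#' Monitor-chamber stability report
#'
#' Reduces ion-chamber readings of the static, arc and sweeping-gap
#' (gravity) deliveries into the standard stability ratios: per MU level
#' and energy, the mean arc reading (over rotation senses) against the
#' static reading; the MU linearity deviation between the low and high MU
#' levels of the static fields; and, for the gravity test, each reading
#' against the mean of the static-angle readings.
#'
#' @param static_readings Tibble with columns `energy`, `mu`, `reading`.
#' @param arc_readings Tibble with columns `energy`, `mu`, `sense`
#'   (e.g. `"CW"`/`"CCW"`), `reading`.
#' @param dmlc_readings Optional tibble with columns `angle` (degrees, or
#'   the label `"arc"`) and `reading` for the moving-gap gravity test.
#' @param digits Rounding for the presentation columns (raw ratios are
#'   kept alongside).
#' @return A `chamber_report`: list of tibbles `arc_static` (ratio per
#'   energy and MU level), `linearity` (deviation fraction per energy) and
#'   `dmlc` (ratio per angle vs the static average), or `NULL` where the
#'   inputs were not supplied.
#' @examples
#' st <- tibble::tibble(energy = "6 MV", mu = c(36, 1000),
#'                      reading = c(6.361, 176.70))
#' ar <- tibble::tibble(energy = "6 MV", mu = rep(c(36, 1000), 2),
#'                      sense = rep(c("CW", "CCW"), each = 2),
#'                      reading = c(6.325, 176.94, 6.324, 176.82))
#' chamber_report(st, ar)$arc_static$ratio_rounded # 0.994 1.001
#' @export
chamber_report <- function(static_readings, arc_readings,
                           dmlc_readings = NULL, digits = 3) {
  st <- tibble::as_tibble(static_readings)
  ar <- tibble::as_tibble(arc_readings)
  joined <- ar |>
    dplyr::group_by(.data$energy, .data$mu) |>
    dplyr::summarise(arc_mean = mean(.data$reading), .groups = "drop") |>
    dplyr::left_join(st, by = c("energy", "mu"))
  if (any(is.na(joined$reading))) {
    stop("missing static reference reading for an arc condition", call. = FALSE)
  }
  arc_static <- joined |>
    dplyr::mutate(
      ratio = .data$arc_mean / .data$reading,
      ratio_rounded = round_half_up(.data$ratio, digits)
    )

  linearity <- st |>
    dplyr::group_by(.data$energy) |>
    dplyr::summarise(
      mu_lo = min(.data$mu), mu_hi = max(.data$mu),
      deviation = abs(
        (.data$reading[which.max(.data$mu)] / max(.data$mu)) /
          (.data$reading[which.min(.data$mu)] / min(.data$mu)) - 1
      ),
      .groups = "drop"
    )

  dmlc <- NULL
  if (!is.null(dmlc_readings)) {
    dm <- tibble::as_tibble(dmlc_readings)
    static_rows <- suppressWarnings(!is.na(as.numeric(dm$angle)))
    ref <- mean(dm$reading[static_rows])
    dmlc <- dm |>
      dplyr::mutate(
        ratio = .data$reading / ref,
        ratio_rounded = round_half_up(.data$ratio, digits)
      )
  }
  structure(
    list(arc_static = arc_static, linearity = linearity, dmlc = dmlc),
    class = "chamber_report"
  )
}

#' @export
print.chamber_report <- function(x, ...) {
  cat("<chamber_report>\n  arc/static ratios:\n")
  print(x$arc_static[, c("energy", "mu", "ratio_rounded")])
  cat(sprintf(
    "  linearity deviation: %s\n",
    paste(sprintf("%s %.2f%%", x$linearity$energy,
                  100 * x$linearity$deviation), collapse = ", ")
  ))
  if (!is.null(x$dmlc)) {
    cat("  gravity-gap ratios vs static average:\n")
    print(x$dmlc[, c("angle", "ratio_rounded")])
  }
  invisible(x)
}

#' Imager central-axis stability report
#'
#' Projects the beam central axis onto the imaging panel at several gantry
#' angles and reports each angle's deviation from the mean, per axis --
#' the sag check that qualifies the panel for leaf-position work (the
#' leaves move along the cross-plane axis X).
#'
#' @param centers Tibble with columns `angle` (degrees) and the measured
#'   centre coordinates `x`, `y` (cm).
#' @return Tibble: `angle`, `x`, `y`, `x_dev`, `y_dev` (cm from the mean).
#' @examples
#' center_pixel_report(tibble::tibble(
#'   angle = c(180, 90, 270, 0), x = c(13.06, 13.06, 13.04, 13.06),
#'   y = c(13.37, 13.27, 13.27, 13.16)
#' ))
#' @export
center_pixel_report <- function(centers) {
  centers <- tibble::as_tibble(centers)
  if (nrow(centers) < 2) stop("need centres at >= 2 angles", call. = FALSE)
  dplyr::mutate(
    centers,
    x_dev = .data$x - mean(.data$x),
    y_dev = .data$y - mean(.data$y)
  )
}
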