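#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fluence image
#'
#' @param object A `fluence_image`.
#' @param ... Unused.
#' @return A ggplot raster of the fluence with isocenter-plane axes.
#' @method autoplot fluence_image
#' @export
autoplot.fluence_image <- function(object, ...) {
  df <- tidyr::expand_grid(y = object$y, x = object$x)
  df$fluence <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$fluence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "cross-plane x (cm)", y = "in-plane y (cm)",
      title = object$meta$plan
    )
}

#' Plot a delivery trace
#'
#' @param object A `delivery_trace`.
#' @param ... Unused.
#' @return A ggplot of cumulative MU, gantry angle and the extreme leaf
#'   positions against time, faceted per quantity.
#' @method autoplot delivery_trace
#' @export
autoplot.delivery_trace <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(
    td[, c("time", "cum_mu", "gantry", "leaf_a_min", "leaf_b_max")],
    -"time",
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = sprintf("delivery trace: %s", object$plan_name)
    )
}

#' Plot a strip report
#'
#' @param object A `strip_report` from [strip_stats()].
#' @param ... Unused.
#' @return A ggplot of per-strip mean with SD error bars against the 100%
#'   reference line.
#' @method autoplot strip_report
#' @export
autoplot.strip_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$index), .data$mean)) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
    )) +
    ggplot2::labs(x = "strip", y = "normalized dose (%)")
}

#' Plot a cross-plane profile
#'
#' @param profile Tibble with `x` and `value` (e.g. [extract_profile()]).
#' @param junctions Optional junction positions to mark, cm.
#' @return A ggplot line plot.
#' @export
plot_profile <- function(profile, junctions = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cross-plane x (cm)", y = "fluence")
  if (!is.null(junctions)) {
    p <- p + ggplot2::geom_vline(
      xintercept = junctions,
      linetype = 3, colour = "red"
    )
  }
  p
}

#' Tidy a chamber report into one long table
#'
#' @param x A `chamber_report`.
#' @param ... Unused.
#' @return A tibble with columns `check`, `condition`, `value`.
#' @method tidy chamber_report
#' @export
tidy.chamber_report <- function(x, ...) {
  out <- list(
    tibble::tibble(
      check = "arc_static",
      condition = sprintf("%s %g MU", x$arc_static$energy, x$arc_static$mu),
      value = x$arc_static$ratio
    ),
    tibble::tibble(
      check = "linearity",
      condition = x$linearity$energy,
      value = x$linearity$deviation
    )
  )
  if (!is.null(x$dmlc)) {
    out <- c(out, list(tibble::tibble(
      check = "dmlc_gravity",
      condition = as.character(x$dmlc$angle),
      value = x$dmlc$ratio
    )))
  }
  dplyr::bind_rows(out)
}
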