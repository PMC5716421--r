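#' Analyse leaf-reversal junctions
#'
#' Quantifies the local over- and under-dose that leaf over-travel
#' produces at programmed direction reversals, on a profile normalized by
#' the slow-reference delivery (percent). The profile is smoothed with a
#' 3-pixel moving average first. For every reversal the generator recorded
#' (aperture edge, coincident turn count, nominal pass count), the peak
#' overdose and trough underdose near the turn are reported, plus an
#' over-travel estimate from inverting the triangular excursion model.
#'
#' A turn overshooting by `delta` at leaf speed `v` redistributes open
#' time near the leading aperture edge: the net gain there integrates to
#' `2 delta^2 / v` per turn (and an equal loss appears one gap-width away
#' at the trailing edge). Against the local nominal open time
#' `p * gap / v` (`p` nominal passes), the fractional excess area around
#' an edge with `n` coincident turns is `2 n delta^2 / (p gap)`, so
#' `delta = sqrt(area * p * gap / (2 n))`. When two opposite turns share a
#' junction, one turn's trailing-edge loss overlaps the other's
#' leading-edge gain and the net fluence excess largely cancels; such
#' edges are flagged `interference` and excluded from the plan-level
#' estimate (the attribute `overtravel_mm`, the median over clean edges).
#'
#' @param profile Normalized profile tibble (`x` cm, `value` percent).
#' @param plan The generating reversal-test `vmat_plan` (its `$meta$turns`
#'   and `$meta$gap` drive the analysis).
#' @param smooth_n Smoothing window, pixels (default 3).
#' @param window Half-width of the excess-integration window around each
#'   edge, cm.
#' @param rescale Rescale the profile so its median reads 100 before
#'   analysis (default `TRUE`: the test-to-reference ratio of two
#'   deliveries of the same pattern at different speeds is constant but
#'   not unity, and simulated fluence carries no absolute scale).
#' @return A `reversal_report` tibble: one row per distinct reversal edge
#'   with `junction` (nearest programmed junction or oscillation centre),
#'   `edge`, `n_turns`, `local_passes`, `interference`, `overdose_pct`,
#'   `underdose_pct`, `rate_pct_per_reversal` and `overtravel_mm`
#'   (`NA` on interfered edges); the plan-level estimate is attached as
#'   attribute `overtravel_mm`.
#' @export
reversal_analysis <- function(profile, plan, smooth_n = 3, window = 0.25,
                              rescale = TRUE) {
  if (rescale) {
    keep <- profile$value > 0.05 * max(profile$value, na.rm = TRUE)
    profile$value <- 100 * profile$value /
      stats::median(profile$value[keep], na.rm = TRUE)
  }
  turns <- plan$meta$turns
  gap <- plan$meta$gap
  if (is.null(turns)) stop("plan carries no reversal metadata", call. = FALSE)
  marks <- c(plan$meta$junctions, plan$meta$osc_centre)
  profile <- profile[!is.na(profile$value), ] # masked pixels carry no signal
  pitch <- stats::median(diff(profile$x))
  sm <- moving_average(profile$value, smooth_n)

  trailing <- turns$position - turns$direction * gap / 2
  edges <- turns |>
    dplyr::group_by(.data$edge, .data$direction, .data$position) |>
    dplyr::summarise(
      n_turns = dplyr::n(),
      local_passes = .data$local_passes[1],
      .groups = "drop"
    )
  feature_x <- unique(c(edges$edge, trailing))
  out <- purrr::map_dfr(seq_len(nrow(edges)), function(k) {
    e <- edges$edge[k]
    interfered <- any(abs(trailing - e) < window + 0.05)
    # clip the integration window at half the distance to the nearest
    # other reversal feature so neighbouring excursions do not bleed in
    others <- feature_x[abs(feature_x - e) > 1e-9]
    w_l <- min(window, suppressWarnings(min((e - others[others < e]) / 2)))
    w_r <- min(window, suppressWarnings(min((others[others > e] - e) / 2)))
    sel <- which(profile$x >= e - w_l & profile$x <= e + w_r)
    under_sel <- which(abs(profile$x - edges$position[k]) <= gap / 2 + 0.3)
    excess <- pmax(sm[sel] - 100, 0)
    area <- sum(excess) * pitch / 100 # fractional excess area, cm
    delta <- sqrt(area * edges$local_passes[k] * gap / (2 * edges$n_turns[k]))
    over <- max(sm[sel]) - 100
    tibble::tibble(
      junction = marks[which.min(abs(marks - edges$position[k]))],
      edge = e, n_turns = edges$n_turns[k],
      local_passes = edges$local_passes[k],
      interference = interfered,
      overdose_pct = over,
      underdose_pct = 100 - min(sm[under_sel]),
      rate_pct_per_reversal = over / edges$n_turns[k],
      overtravel_mm = if (interfered) NA_real_ else delta * 10
    )
  })
  out <- dplyr::arrange(out, .data$edge)
  class(out) <- c("reversal_report", class(out))
  attr(out, "overtravel_mm") <-
    stats::median(out$overtravel_mm[!out$interference])
  out
}

#' Analyse dose-rate change junctions
#'
#' Measures, around each strip junction of a dose-rate change test, the
#' signed maximum excursion of the normalized profile and the widths over
#' which the dose stays beyond +/-2% and +/-3% -- the transverse distance
#' an under/overdose needs to return to unity after the controller
#' switches dose-rate bins (leaf speed times the switching lag, e.g.
#' 2.5 mm at 1 cm/s and 0.25 s).
#'
#' @param profile Normalized profile tibble (`x` cm, `value` percent).
#' @param junctions Junction positions, cm.
#' @param thresholds Excursion thresholds, percent (default `c(2, 3)`).
#' @param window Half-width of the junction window, cm.
#' @param smooth_n Smoothing window in pixels (default 3).
#' @param rescale Rescale the profile so its median reads 100 first
#'   (default `TRUE`; see [reversal_analysis()]).
#' @return A `transition_report` tibble: `junction`,
#'   `max_excursion_pct` (signed), and one `width_<t>pct_mm` column per
#'   threshold.
#' @export
transition_analysis <- function(profile, junctions, thresholds = c(2, 3),
                                window = 1.5, smooth_n = 3, rescale = TRUE) {
  profile <- profile[!is.na(profile$value), ]
  if (rescale) {
    keep <- profile$value > 0.05 * max(profile$value)
    profile$value <- 100 * profile$value / stats::median(profile$value[keep])
  }
  pitch <- stats::median(diff(profile$x))
  sm <- moving_average(profile$value, smooth_n)
  out <- purrr::map_dfr(junctions, function(j) {
    sel <- which(abs(profile$x - j) <= window & !is.na(sm))
    dev <- sm[sel] - 100
    peak <- dev[which.max(abs(dev))]
    row <- tibble::tibble(junction = j, max_excursion_pct = peak)
    for (th in thresholds) {
      row[[sprintf("width_%gpct_mm", th)]] <- sum(abs(dev) > th) * pitch * 10
    }
    row
  })
  class(out) <- c("transition_report", class(out))
  out
}
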