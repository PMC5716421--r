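#' Read and write plans, images and configuration
#'
#' JSON is the canonical plan format and round-trips to full precision;
#' CSV is a lossy convenience export of the control-point table only.
#' Images are exchanged as plain-text matrices with an axis header (diff-
#' friendly) or 32-bit float TIFF. Machine limits travel as YAML blocks
#' whose keys mirror [machine_limits()].
#'
#' @name vmatqa_io
NULL

# all-NA numeric columns deserialize as logical; restore them
numeric_na_cols <- function(df) {
  df <- tibble::as_tibble(df)
  df[] <- lapply(df, function(col) {
    if (is.logical(col) && all(is.na(col))) as.numeric(col) else col
  })
  df
}

plan_to_list <- function(plan) {
  meta <- plan$meta
  if (!is.null(meta$turns)) meta$turns <- as.data.frame(meta$turns)
  list(
    format = "vmatqa-plan-v1",
    name = plan$name,
    energy_label = plan$energy_label,
    notes = plan$notes,
    meta = meta,
    strip_specs = if (is.null(plan$strip_specs)) NULL else as.data.frame(plan$strip_specs),
    control_points = as.data.frame(plan$control_points)
  )
}

#' @param plan A `vmat_plan`.
#' @param path File path.
#' @rdname vmatqa_io
#' @export
write_plan_json <- function(plan, path) {
  jsonlite::write_json(plan_to_list(plan), path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname vmatqa_io
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || !identical(obj$format, "vmatqa-plan-v1")) {
    stop("not a vmatqa plan file: ", path, call. = FALSE)
  }
  cps <- tibble::as_tibble(obj$control_points)
  need <- c("cum_mu", "gantry", leaf_bank_cols("a"), leaf_bank_cols("b"))
  miss <- setdiff(need, names(cps))
  if (length(miss) > 0) {
    stop(
      "plan file lacks control-point fields: ",
      paste(utils::head(miss, 5), collapse = ", "), call. = FALSE
    )
  }
  meta <- obj$meta
  if (!is.null(meta$turns)) meta$turns <- tibble::as_tibble(meta$turns)
  if (!is.null(meta$errors)) {
    meta$errors <- lapply(meta$errors, function(e) e[!vapply(e, is.null, logical(1))])
  }
  vmat_plan(
    name = obj$name, control_points = cps,
    energy_label = obj$energy_label %||% "6 MV",
    strip_specs = if (is.null(obj$strip_specs)) NULL else numeric_na_cols(obj$strip_specs),
    meta = meta %||% list(), notes = obj$notes %||% ""
  )
}

#' @rdname vmatqa_io
#' @export
write_plan_csv <- function(plan, path) {
  utils::write.csv(as.data.frame(plan$control_points), path, row.names = FALSE)
  invisible(path)
}

#' @param name,energy_label Plan identity for the reassembled plan (the CSV
#'   stores only control points).
#' @rdname vmatqa_io
#' @export
read_plan_csv <- function(path, name = "imported", energy_label = "6 MV") {
  cps <- tibble::as_tibble(utils::read.csv(path))
  vmat_plan(name = name, control_points = cps, energy_label = energy_label)
}

#' @param limits A [machine_limits()] object.
#' @rdname vmatqa_io
#' @export
write_limits_yaml <- function(limits, path) {
  yaml::write_yaml(unclass(limits), path)
  invisible(path)
}

#' @rdname vmatqa_io
#' @export
read_limits_yaml <- function(path) {
  do.call(machine_limits, yaml::read_yaml(path))
}

#' @param image A `fluence_image`.
#' @rdname vmatqa_io
#' @export
write_image_txt <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vmatqa fluence image v1",
    paste("# plan:", image$meta$plan %||% "unknown"),
    paste("# x_cm:", paste(format(image$x, digits = 10, trim = TRUE), collapse = " ")),
    paste("# y_cm:", paste(format(image$y, digits = 10, trim = TRUE), collapse = " "))
  ), con)
  utils::write.table(
    format(image$values, digits = 9, trim = TRUE), con,
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname vmatqa_io
#' @export
read_image_txt <- function(path) {
  hdr <- readLines(path, n = 4)
  if (!startsWith(hdr[1], "# vmatqa fluence image")) {
    stop("not a vmatqa image file: ", path, call. = FALSE)
  }
  grab <- function(line, tag) {
    as.numeric(strsplit(sub(paste0("# ", tag, ": "), "", line), " +")[[1]])
  }
  x <- grab(hdr[3], "x_cm")
  y <- grab(hdr[4], "y_cm")
  vals <- as.matrix(utils::read.table(path, skip = 4))
  dimnames(vals) <- NULL
  new_fluence_image(vals, x, y,
    meta = list(plan = sub("# plan: ", "", hdr[2]))
  )
}

#' @param scale Stored alongside a TIFF so absolute fluence can be
#'   recovered; defaults to the image maximum.
#' @rdname vmatqa_io
#' @export
write_image_tiff <- function(image, path, scale = NULL) {
  if (is.null(scale)) scale <- max(image$values, 1e-12)
  tiff::writeTIFF(image$values / scale, path,
    bits.per.sample = 32L, compression = "none"
  )
  invisible(path)
}

#' @param pitch Pixel pitch (cm) to reconstruct axes from a bare TIFF.
#' @rdname vmatqa_io
#' @export
read_image_tiff <- function(path, pitch, scale = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  nx <- ncol(m)
  ny <- nrow(m)
  new_fluence_image(
    m * scale,
    x = (seq_len(nx) - (nx + 1) / 2) * pitch,
    y = (seq_len(ny) - (ny + 1) / 2) * pitch,
    meta = list(plan = "tiff-import")
  )
}

#' Bundled example commissioning readings
#'
#' Small plain-text tables of example measured readings from an
#' Elekta-style linac commissioning session, used by the worked examples
#' and the desk-scale report checks: EPID central-axis positions by gantry
#' angle, monitor-chamber readings for static/arc fields, gravity-gap
#' chamber readings, and picket-fence peak positions by acquisition.
#'
#' @param name One of `"epid_centers"`, `"chamber_static"`, `"chamber_arc"`,
#'   `"dmlc_gravity"`, `"picket_peaks"`.
#' @return A tibble.
#' @export
reference_readings <- function(name = c("epid_centers", "chamber_static",
                                        "chamber_arc", "dmlc_gravity",
                                        "picket_peaks")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "vmatqa")
  if (path == "") stop("bundled readings not found: ", name, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Build a deterministic test fixture
#'
#' Generates a named test plan, simulates it noiselessly (unless the
#' config injects errors) and renders the fluence image(s), bundling the
#' analyzer-ready metadata. Deterministic for a fixed seed.
#'
#' @param test_name One of the names listed by `make_fixture("list")`.
#' @param config Optional overrides: `limits`, `detector`, `errors`, `dt`.
#' @param seed Integer seed (recorded in provenance and used for any
#'   stochastic render component).
#' @return A list with elements among `plan`, `plans`, `image`, `images`,
#'   `reference`, plus `seed` and `test_name`.
#' @export
make_fixture <- function(test_name, config = list(), seed = 1L) {
  tests <- c(
    "picket_fence_static", "picket_fence_arc", "picket_fence_errors",
    "dr_gs_strips", "mlc_speed_strips", "reversal",
    "dr_change_increase", "dr_change_decrease", "gravity_gap", "open_field"
  )
  if (identical(test_name, "list")) {
    return(tests)
  }
  if (!test_name %in% tests) {
    stop(
      "unknown test '", test_name, "'; available: ",
      paste(tests, collapse = ", "), call. = FALSE
    )
  }
  limits <- config$limits %||% machine_limits()
  errors <- config$errors %||% error_model()
  dt <- config$dt %||% 0.01
  det <- config$detector %||% switch(test_name,
    dr_gs_strips = detector_model("diode_array"),
    detector_model("epid")
  )
  sim <- function(plan) {
    render_fluence(simulate_delivery(plan, limits, errors, dt), det, seed = seed)
  }
  out <- switch(test_name,
    picket_fence_static = {
      plan <- gen_picket_fence(limits = limits)
      list(plan = plan, image = sim(plan))
    },
    picket_fence_arc = {
      plan <- gen_picket_fence(arc = 356, limits = limits)
      list(plan = plan, image = sim(plan))
    },
    picket_fence_errors = {
      plan <- gen_picket_fence(
        errors = list(
          list(pair = 20, widen_to = 0.15),
          list(pair = 25, shift = 0.05)
        ),
        arc = 356, limits = limits
      )
      list(plan = plan, image = sim(plan))
    },
    dr_gs_strips = {
      plan <- gen_dr_gs_strip_test(limits = limits)
      open <- gen_utility_fields("open_field", limits = limits)
      list(plan = plan, image = sim(plan), reference = sim(open))
    },
    mlc_speed_strips = {
      plan <- gen_mlc_speed_strip_test(limits = limits)
      open <- gen_utility_fields("open_field", limits = limits)
      list(plan = plan, image = sim(plan), reference = sim(open))
    },
    reversal = {
      plans <- gen_reversal_test(limits = limits)
      imgs <- lapply(plans, sim)
      list(plans = plans, images = imgs)
    },
    dr_change_increase = ,
    dr_change_decrease = {
      dirn <- sub("dr_change_", "", test_name)
      pair <- gen_dr_change_test(dirn, limits = limits)
      list(
        plan = pair$test, reference_plan = pair$reference,
        image = sim(pair$test), reference = sim(pair$reference)
      )
    },
    gravity_gap = {
      plan <- gen_utility_fields("dmlc_gravity", limits = limits)
      list(plan = plan, image = sim(plan))
    },
    open_field = {
      plan <- gen_utility_fields("open_field", limits = limits)
      list(plan = plan, image = sim(plan))
    }
  )
  c(out, list(seed = seed, test_name = test_name))
}
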