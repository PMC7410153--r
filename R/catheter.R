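## Hagen-Poiseuille sizing of distal-resistance catheters.  A catheter of
## inner radius r (cm) and length L (cm) carrying fully developed laminar
## flow of a fluid with viscosity mu (poise) has hydraulic resistance
##   R = 8 mu L / (pi r^4)   [dynes.s/cm^5]
## which is inverted exactly to solve for the length realizing a target
## resistance.  Entrance/exit losses and turbulence are ignored; at the
## sub-10 mL/min per-catheter flows of a coronary phantom the Reynolds
## number stays well inside the laminar regime.

#' Hydraulic resistance of a cylindrical catheter (Hagen-Poiseuille)
#'
#' Computes `R = 8 * mu * L / (pi * r^4)` in dynes.s/cm5 for laminar flow.
#'
#' @param radius_cm Inner lumen radius in cm; must be > 0. Vectorized.
#' @param length_cm Catheter length in cm; must be >= 0. Vectorized.
#' @param fluid A [fluid_properties()] object (or a bare viscosity in poise).
#' @return Hydraulic resistance in dynes.s/cm5.
#' @examples
#' poiseuille_resistance(0.06, 34.9)          # ~254,000 dynes.s/cm5
#' poiseuille_resistance(0.09, 20.1)
#' @seealso [poiseuille_length()] for the exact inverse.
#' @export
poiseuille_resistance <- function(radius_cm, length_cm, fluid = fluid_properties()) {
  fluid <- .as_fluid(fluid)
  stopifnot(is.numeric(radius_cm), is.numeric(length_cm))
  if (any(!is.finite(radius_cm)) || any(radius_cm <= 0)) {
    stop("radius_cm must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(length_cm)) || any(length_cm < 0)) {
    stop("length_cm must be non-negative and finite", call. = FALSE)
  }
  8 * fluid$viscosity_poise * length_cm / (pi * radius_cm^4)
}

#' Catheter length realizing a target hydraulic resistance
#'
#' Exact algebraic inverse of [poiseuille_resistance()]:
#' `L = R * pi * r^4 / (8 * mu)`.
#'
#' @param target Target resistance in dynes.s/cm5; must be >= 0. Vectorized.
#' @param radius_cm Inner lumen radius in cm; must be > 0. Vectorized.
#' @inheritParams poiseuille_resistance
#' @return Length in cm.
#' @examples
#' poiseuille_length(254250, 0.071)   # ~68.5 cm
#' @export
poiseuille_length <- function(target, radius_cm, fluid = fluid_properties()) {
  fluid <- .as_fluid(fluid)
  stopifnot(is.numeric(target), is.numeric(radius_cm))
  if (any(!is.finite(target)) || any(target < 0)) {
    stop("target resistance must be non-negative and finite", call. = FALSE)
  }
  if (any(!is.finite(radius_cm)) || any(radius_cm <= 0)) {
    stop("radius_cm must be positive and finite", call. = FALSE)
  }
  target * pi * radius_cm^4 / (8 * fluid$viscosity_poise)
}

#' Fit the working-fluid viscosity to a catheter length table
#'
#' One-dimensional minimization of the mean relative error between predicted
#' Poiseuille lengths and a reference sizing table, over viscosity. Used to
#' recover the (unstated) viscosity behind [reference_length_table()]; with
#' the shipped table the optimum lands at ~0.037 poise, confirming the table
#' is Poiseuille-consistent and fixing the package default.
#'
#' @param table A data.frame with columns `resistance`, `radius_cm`,
#'   `length_cm`; defaults to [reference_length_table()].
#' @param interval Search interval for viscosity in poise.
#' @return A list with `viscosity_poise` (the minimizer) and
#'   `mean_relative_error` at the optimum.
#' @examples
#' fit_viscosity()$viscosity_poise
#' @export
fit_viscosity <- function(table = reference_length_table(),
                          interval = c(0.005, 0.10)) {
  stopifnot(all(c("resistance", "radius_cm", "length_cm") %in% names(table)),
            nrow(table) > 0)
  objective <- function(mu) {
    pred <- poiseuille_length(table$resistance, table$radius_cm,
                              fluid_properties(mu))
    mean(abs(pred - table$length_cm) / table$length_cm)
  }
  opt <- stats::optimize(objective, interval = interval, tol = 1e-8)
  list(viscosity_poise = opt$minimum, mean_relative_error = opt$objective)
}

#' Catheter resistance needed distal to a compliance chamber
#'
#' The outflow chamber contributes a small series resistance of its own, so
#' the catheter must supply only the remainder: `coronary - chamber`.
#' Configurations where the chamber alone meets or exceeds the coronary
#' target are non-physical for this hardware and are rejected.
#'
#' @param coronary Target coronary distal resistance, dynes.s/cm5.
#' @param chamber Measured chamber resistance, dynes.s/cm5 (>= 0).
#' @return Required catheter resistance, dynes.s/cm5.
#' @examples
#' required_distal_resistance(254250, 1671)   # 252579
#' @export
required_distal_resistance <- function(coronary, chamber) {
  stopifnot(is.numeric(coronary), is.numeric(chamber))
  if (any(chamber < 0)) stop("chamber resistance must be >= 0", call. = FALSE)
  if (any(chamber >= coronary)) {
    stop("chamber resistance must be smaller than the coronary target; ",
         "the catheter cannot supply a negative resistance", call. = FALSE)
  }
  coronary - chamber
}

#' Catheter catalog
#'
#' Available catheter stock: inner lumen radius per French size and the
#' length range that is commercially available. The default catalog is
#' 4/5/6 Fr with radii 0.06/0.071/0.09 cm and a 112 cm maximum stock length
#' (the longest commonly stocked catheter). The default minimum is 0: stock
#' can always be cut shorter, so only over-length designs are infeasible.
#' Supply a positive `min_length_cm` to model stock that cannot be trimmed.
#'
#' @param entries A data.frame with columns `fr`, `inner_radius_cm`,
#'   `min_length_cm`, `max_length_cm`. Radii must be strictly increasing
#'   with French size.
#' @return An object of class `catheter_catalog` (a data.frame).
#' @examples
#' catheter_catalog()
#' @export
catheter_catalog <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- data.frame(
      fr = c(4L, 5L, 6L),
      inner_radius_cm = c(0.06, 0.071, 0.09),
      min_length_cm = 0,
      max_length_cm = 112
    )
  }
  stopifnot(is.data.frame(entries), nrow(entries) >= 1,
            all(c("fr", "inner_radius_cm", "min_length_cm", "max_length_cm")
                %in% names(entries)))
  entries <- entries[order(entries$fr), , drop = FALSE]
  if (any(entries$inner_radius_cm <= 0)) stop("radii must be > 0", call. = FALSE)
  if (any(diff(entries$inner_radius_cm) <= 0)) {
    stop("inner radii must be strictly increasing with French size", call. = FALSE)
  }
  if (any(entries$min_length_cm >= entries$max_length_cm)) {
    stop("min_length_cm must be < max_length_cm", call. = FALSE)
  }
  rownames(entries) <- NULL
  class(entries) <- c("catheter_catalog", "data.frame")
  entries
}

#' Read a catheter catalog from a YAML or JSON config file
#'
#' Expects a top-level `catalog:` list of entries with keys `fr`,
#' `inner_radius_cm`, `min_length_cm`, `max_length_cm`; an optional top-level
#' `fluid: {viscosity_poise, density}` block is returned alongside.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `catalog` ([catheter_catalog()]) and `fluid`
#'   ([fluid_properties()], defaulted if absent).
#' @export
read_catalog_config <- function(path) {
  cfg <- .read_config(path)
  if (is.null(cfg$catalog)) stop("config has no 'catalog' key: ", path, call. = FALSE)
  entries <- do.call(rbind, lapply(cfg$catalog, function(e) {
    as.data.frame(e[c("fr", "inner_radius_cm", "min_length_cm", "max_length_cm")])
  }))
  list(catalog = catheter_catalog(entries),
       fluid = .as_fluid(cfg$fluid %||% list()))
}

.read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
}

#' Design catheter options for a target distal resistance
#'
#' For each radius in the catalog, solves the Poiseuille length that realizes
#' the (chamber-corrected) target and checks it against the catalog's length
#' window. Options outside the window are kept but flagged infeasible with a
#' reason ("exceeds max length -- use smaller Fr" / "below min length -- use
#' larger Fr"). Options are sorted by absolute relative error, feasible first
#' among ties, then by French size.
#'
#' @param target Target distal resistance in dynes.s/cm5, or a one-row
#'   data.frame with a `resistance` column (e.g. a row of
#'   [activity_presets()]).
#' @param catalog A [catheter_catalog()].
#' @param fluid A [fluid_properties()].
#' @param chamber_resistance Optional chamber resistance (dynes.s/cm5) to
#'   subtract from the target before sizing (default 0).
#' @return An object of class `design_result`: a data.frame with one row per
#'   catalog radius and columns `fr`, `radius_cm`, `length_cm`,
#'   `achieved_resistance`, `relative_error`, `feasible`,
#'   `infeasibility_reason`, plus attributes `target` and
#'   `corrected_target`.
#' @examples
#' design_for_target(254250)                      # rest LAD
#' design_for_target(479000)                      # rest RCA: only 4 Fr feasible
#' @export
design_for_target <- function(target, catalog = catheter_catalog(),
                              fluid = fluid_properties(),
                              chamber_resistance = 0) {
  if (is.data.frame(target)) {
    stopifnot(nrow(target) == 1L, "resistance" %in% names(target))
    target <- target$resistance
  }
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  catalog <- catheter_catalog(as.data.frame(catalog))
  fluid <- .as_fluid(fluid)
  corrected <- if (chamber_resistance > 0) {
    required_distal_resistance(target, chamber_resistance)
  } else {
    target
  }

  len <- poiseuille_length(corrected, catalog$inner_radius_cm, fluid)
  achieved <- poiseuille_resistance(catalog$inner_radius_cm, len, fluid)
  feasible <- len >= catalog$min_length_cm & len <= catalog$max_length_cm
  reason <- rep(NA_character_, nrow(catalog))
  reason[len > catalog$max_length_cm] <- "exceeds max length -- use smaller Fr"
  reason[len < catalog$min_length_cm] <- "below min length -- use larger Fr"

  out <- data.frame(
    fr = catalog$fr,
    radius_cm = catalog$inner_radius_cm,
    length_cm = len,
    achieved_resistance = achieved,
    relative_error = (achieved - corrected) / corrected,
    feasible = feasible,
    infeasibility_reason = reason,
    stringsAsFactors = FALSE
  )
  # errors below 1e-12 are numerically exact: rank as ties so feasibility decides
  err_key <- round(abs(out$relative_error), 12)
  ord <- order(err_key, !out$feasible, out$fr)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "target") <- target
  attr(out, "corrected_target") <- corrected
  class(out) <- c("design_result", "data.frame")
  out
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("Catheter design for target %.0f dynes.s/cm5", attr(x, "target")))
  if (!identical(attr(x, "target"), attr(x, "corrected_target"))) {
    cat(sprintf(" (chamber-corrected to %.0f)", attr(x, "corrected_target")))
  }
  cat("\n")
  y <- as.data.frame(x)
  y$length_cm <- round(y$length_cm, 1)
  y$achieved_resistance <- round(y$achieved_resistance)
  y$relative_error <- signif(y$relative_error, 3)
  print(y, ...)
  invisible(x)
}

#' Build a quantized catheter set
#'
#' Designs one catheter per multiple of `step` in `[r_min, r_max]`
#' (inclusive), the bench practice of stocking resistances in round steps so
#' any target can be approximated by the nearest stocked catheter. Defaults:
#' 50,000 to 300,000 in steps of 10,000 dynes.s/cm5.
#'
#' @param r_min,r_max Range of resistances, dynes.s/cm5; `0 < r_min <= r_max`.
#' @param step Quantization step, dynes.s/cm5; must be > 0.
#' @inheritParams design_for_target
#' @return A list of [design_for_target()] results, named by target.
#' @examples
#' length(build_quantized_set())    # 26 targets
#' @export
build_quantized_set <- function(r_min = 50000, r_max = 300000, step = 10000,
                                catalog = catheter_catalog(),
                                fluid = fluid_properties()) {
  stopifnot(is.numeric(r_min), is.numeric(r_max), is.numeric(step))
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (!(r_min > 0 && r_min <= r_max)) stop("need 0 < r_min <= r_max", call. = FALSE)
  first <- ceiling(r_min / step) * step
  if (first > r_max) return(list())
  targets <- seq(first, r_max, by = step)
  out <- lapply(targets, design_for_target, catalog = catalog, fluid = fluid)
  names(out) <- format(targets, scientific = FALSE, trim = TRUE)
  out
}

#' Relative error from quantizing a resistance target to a stocked step
#'
#' Distance from `true_target` to the nearest multiple of `step`, as a
#' fraction of `true_target`; ties between neighboring multiples round up.
#' Bounded by `step / (2 * true_target)`.
#'
#' @param true_target True resistance, dynes.s/cm5 (> 0). Vectorized.
#' @param step Quantization step, dynes.s/cm5 (> 0).
#' @return Fractional error (dimensionless).
#' @examples
#' quantization_error(254250, 10000)   # 0.0167
#' @export
quantization_error <- function(true_target, step = 10000) {
  stopifnot(is.numeric(true_target), is.numeric(step))
  if (any(true_target <= 0)) stop("true_target must be > 0", call. = FALSE)
  if (any(step <= 0)) stop("step must be > 0", call. = FALSE)
  nearest <- floor(true_target / step + 0.5) * step   # ties round up
  abs(nearest - true_target) / true_target
}
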