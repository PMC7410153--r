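#' coroflow: distal-resistance design and 0D simulation for coronary flow phantoms
#'
#' @keywords internal
"_PACKAGE"

## Canonical internal unit system is CGS: cm, g, s, dynes.  Resistances are
## dynes.s/cm^5, flows cm^3/s, pressures dynes/cm^2, compliances cm^5/dyne.
## Public constructors and converters accept the clinical units (mmHg, mL/min)
## used by bench instrumentation.

#' Unit conversion constants
#'
#' Fixed constants of the CGS unit bridge: 1 mmHg = 1333.22 dynes/cm2,
#' 1 Pa = 10 dynes/cm2, 1 mL/min = 1/60 cm3/s.
#'
#' @format A named list with elements `mmHg_to_dynes_cm2`, `Pa_to_dynes_cm2`,
#'   `mL_min_to_cm3_s`.
#' @export
unit_constants <- list(
  mmHg_to_dynes_cm2 = 1333.22,
  Pa_to_dynes_cm2   = 10,
  mL_min_to_cm3_s   = 1 / 60
)

# flow units expressed in cm^3/s per unit
.flow_units <- c("mL/min" = 1 / 60, "cm3/s" = 1, "L/min" = 1000 / 60)
# pressure units expressed in dynes/cm^2 per unit
.pressure_units <- c("mmHg" = 1333.22, "dynes/cm2" = 1, "Pa" = 10)

.match_unit <- function(unit, table, what) {
  # tolerate common spellings: "ml/min", "cm^3/s", "dyn/cm^2" ...
  key <- gsub("\\^", "", tolower(unit))
  keys <- gsub("\\^", "", tolower(names(table)))
  i <- match(key, keys)
  if (is.na(i)) {
    stop(sprintf("unknown %s unit '%s'; expected one of: %s",
                 what, unit, paste(names(table), collapse = ", ")),
         call. = FALSE)
  }
  table[[i]]
}

#' Convert volumetric flow rates between units
#'
#' Supported units: `"mL/min"`, `"cm3/s"` (canonical CGS), `"L/min"`.
#' Conversions are exact rational scalings, so composing a conversion with
#' its inverse returns the input to machine precision.
#'
#' @param q Numeric vector of flow values.
#' @param from,to Unit names.
#' @return Numeric vector of converted flows.
#' @examples
#' convert_flow(80, "mL/min", "cm3/s")   # 1.333...
#' convert_flow(2.6667, "cm3/s", "mL/min")
#' @export
convert_flow <- function(q, from = "mL/min", to = "cm3/s") {
  stopifnot(is.numeric(q))
  q * .match_unit(from, .flow_units, "flow") / .match_unit(to, .flow_units, "flow")
}

#' Convert pressures between units
#'
#' Supported units: `"mmHg"`, `"dynes/cm2"` (canonical CGS), `"Pa"`.
#' The mmHg constant is fixed at 1333.22 dynes/cm2 per mmHg.
#'
#' @param p Numeric vector of pressure values.
#' @param from,to Unit names.
#' @return Numeric vector of converted pressures.
#' @examples
#' convert_pressure(100, "mmHg", "dynes/cm2")  # 133322
#' convert_pressure(1, "Pa", "dynes/cm2")      # 10
#' @export
convert_pressure <- function(p, from = "mmHg", to = "dynes/cm2") {
  stopifnot(is.numeric(p))
  p * .match_unit(from, .pressure_units, "pressure") /
    .match_unit(to, .pressure_units, "pressure")
}

#' Working-fluid properties
#'
#' Dynamic viscosity (poise, i.e. g cm-1 s-1) and density (g/cm3) of the
#' loop's working fluid. The default 0.037 poise (3.7 cP) is a blood-analog
#' viscosity: it is the value that makes the Poiseuille catheter-length table
#' shipped with the package self-consistent (see [fit_viscosity()]), and it
#' can be overridden everywhere it is consumed.
#'
#' @param viscosity_poise Dynamic viscosity in poise; must be > 0.
#' @param density Fluid density in g/cm3; must be > 0.
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties()                 # blood-analog default
#' fluid_properties(0.01)             # water at ~20 C
#' @export
fluid_properties <- function(viscosity_poise = 0.037, density = 1.0) {
  stopifnot(is.numeric(viscosity_poise), length(viscosity_poise) == 1L,
            is.finite(viscosity_poise),
            is.numeric(density), length(density) == 1L, is.finite(density))
  if (viscosity_poise <= 0) stop("viscosity must be > 0", call. = FALSE)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  structure(list(viscosity_poise = viscosity_poise, density = density),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Working fluid: viscosity %.4g poise (%.3g cP), density %.3g g/cm3\n",
              x$viscosity_poise, 100 * x$viscosity_poise, x$density))
  invisible(x)
}

.as_fluid <- function(fluid) {
  if (inherits(fluid, "fluid_properties")) return(fluid)
  if (is.numeric(fluid) && length(fluid) == 1L) return(fluid_properties(fluid))
  if (is.list(fluid)) {
    return(fluid_properties(
      viscosity_poise = fluid$viscosity_poise %||% 0.037,
      density = fluid$density %||% 1.0
    ))
  }
  stop("'fluid' must be a fluid_properties object, a viscosity in poise, or a list",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
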