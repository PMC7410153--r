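## Shipped reference values: per-vessel distal coronary-bed resistances for
## three activity states, and the catheter length table they imply under the
## Hagen-Poiseuille law with the default blood-analog fluid.  These are the
## zero-config defaults of the design workflow; every consumer accepts
## user-supplied replacements.

.vessels    <- c("LAD", "LCX", "RCA")
.activities <- c("rest", "light_exercise", "moderate_exercise")

#' Distal coronary resistance presets by vessel and activity state
#'
#' Average distal (capillary-bed) hydraulic resistances of the three main
#' coronary arteries at rest, during light exercise, and during moderate
#' exercise, taken from published lumped-parameter coronary models. Distal
#' resistance decreases with activity (hyperemia): per vessel the values are
#' non-increasing from rest to moderate exercise.
#'
#' @return A data.frame with columns `vessel`, `activity`,
#'   `resistance` (dynes.s/cm5).
#' @examples
#' activity_presets()
#' @export
activity_presets <- function() {
  out <- data.frame(
    vessel   = rep(.vessels, times = 3),
    activity = rep(.activities, each = 3),
    resistance = c(254250, 137000, 479000,   # rest
                   71250,  81750, 121000,    # light exercise
                   29000,  29300,  50300),   # moderate exercise
    stringsAsFactors = FALSE
  )
  class(out) <- c("activity_presets", "data.frame")
  out
}

.check_presets <- function(presets) {
  stopifnot(is.data.frame(presets),
            all(c("vessel", "activity", "resistance") %in% names(presets)))
  missing <- setdiff(
    paste(rep(.vessels, each = 3), rep(.activities, 3), sep = ":"),
    paste(presets$vessel, presets$activity, sep = ":")
  )
  if (length(missing)) {
    stop("presets missing vessel:activity combination(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(presets$resistance <= 0)) stop("preset resistances must be > 0", call. = FALSE)
  for (v in .vessels) {
    r <- vapply(.activities, function(a) .preset_resistance(presets, v, a), numeric(1))
    if (any(diff(r) > 0)) {
      stop(sprintf("preset resistances for %s must be non-increasing from rest to moderate exercise", v),
           call. = FALSE)
    }
  }
  invisible(presets)
}

.preset_resistance <- function(presets, vessel, activity) {
  i <- which(presets$vessel == vessel & presets$activity == activity)
  if (length(i) != 1L) {
    stop(sprintf("no unique preset for vessel '%s', activity '%s'", vessel, activity),
         call. = FALSE)
  }
  presets$resistance[i]
}

#' Reference catheter-length table
#'
#' The published sizing table for distal-resistance catheters: for each vessel
#' and activity state, the catheter length that realizes the preset distal
#' resistance in each of three lumen radii (4/5/6 Fr). Lengths above the
#' commercially available maximum (112 cm in the default catalog) carry
#' `available = FALSE`; those are the cells the source flags as requiring a
#' smaller French size.
#'
#' These printed lengths serve as an external check of the Poiseuille sizing
#' code; they are consumed by [fit_viscosity()] and the validation suite.
#'
#' @return A data.frame with columns `vessel`, `activity`, `resistance`,
#'   `radius_cm`, `length_cm`, `available`.
#' @examples
#' head(reference_length_table())
#' @export
reference_length_table <- function() {
  lengths <- c(
    # r = 0.06, 0.071, 0.09 per row
    34.9, 68.5, 176.95,   # rest LAD  254,250
    18.8, 36.9, 95.3,     # rest LCX  137,000
    65.8, 129.1, 333.3,   # rest RCA  479,000
    9.7, 19.2, 49.5,      # light LAD  71,250
    11.2, 22.0, 56.8,     # light LCX  81,750
    16.6, 32.6, 84.2,     # light RCA 121,000
    3.9, 7.8, 20.1,       # moderate LAD 29,000
    4.0, 7.8, 20.3,       # moderate LCX 29,300
    6.9, 13.5, 35.0       # moderate RCA 50,300
  )
  p <- activity_presets()
  ord <- order(match(p$activity, .activities), match(p$vessel, .vessels))
  p <- p[ord, ]
  out <- data.frame(
    vessel     = rep(p$vessel, each = 3),
    activity   = rep(p$activity, each = 3),
    resistance = rep(p$resistance, each = 3),
    radius_cm  = rep(c(0.06, 0.071, 0.09), times = 9),
    length_cm  = lengths,
    stringsAsFactors = FALSE
  )
  # cells the source marks as not commercially available (length > 112 cm)
  out$available <- !(out$length_cm %in% c(176.95, 129.1, 333.3))
  rownames(out) <- NULL
  out
}
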