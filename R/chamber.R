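## Characterization of the outflow compliance chambers.  Each chamber is
## driven with a constant-flow sweep while the pressure drop across it is
## recorded; the chamber's intrinsic hydraulic resistance is estimated as
## the mean of the per-point ratios dP/Q (headline figure) and, alongside,
## as the through-origin least-squares slope of dP on Q.

#' Constant-flow sweep protocol
#'
#' Inclusive arithmetic sequence of flow setpoints. The default protocol is
#' 80 to 160 mL/min in 20 mL/min increments (five setpoints, 1.33-2.67
#' cm3/s), the sweep used to characterize each chamber on the bench.
#'
#' @param start,stop Sweep bounds in mL/min; `start <= stop`.
#' @param step Increment in mL/min; must be > 0.
#' @return A data.frame with columns `flow_ml_min` and `flow_cm3_s`.
#' @examples
#' sweep_protocol()                # 80 100 120 140 160 mL/min
#' @export
sweep_protocol <- function(start = 80, stop = 160, step = 20) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (start > stop) stop("start must be <= stop", call. = FALSE)
  q <- seq(start, stop, by = step)
  data.frame(flow_ml_min = q, flow_cm3_s = convert_flow(q, "mL/min", "cm3/s"))
}

#' Flow/pressure measurements
#'
#' Builds a validated measurement table in canonical CGS units from paired
#' flow and pressure-drop readings. Pressure drop is inlet minus outlet with
#' the outlet at atmospheric reference unless the caller already differenced.
#'
#' @param flow Flow values.
#' @param pressure_drop Pressure-drop values.
#' @param chamber Chamber label(s), e.g. `"LAD"`; recycled.
#' @param flow_unit,pressure_unit Units of the inputs (see [convert_flow()],
#'   [convert_pressure()]).
#' @return A data.frame with columns `chamber`, `flow_cm3_s`,
#'   `dp_dynes_cm2`.
#' @export
flow_measurements <- function(flow, pressure_drop, chamber = "LAD",
                              flow_unit = "cm3/s",
                              pressure_unit = "dynes/cm2") {
  stopifnot(length(flow) == length(pressure_drop))
  q <- convert_flow(flow, flow_unit, "cm3/s")
  dp <- convert_pressure(pressure_drop, pressure_unit, "dynes/cm2")
  if (any(dp < 0)) stop("pressure drops must be >= 0", call. = FALSE)
  data.frame(chamber = rep_len(as.character(chamber), length(q)),
             flow_cm3_s = q, dp_dynes_cm2 = dp,
             stringsAsFactors = FALSE)
}

#' Read chamber flow-sweep measurements from delimited text
#'
#' Expects a header with `chamber`, `flow_ml_min` (or `flow_cm3_s`) and
#' `dp_mmHg` (or `dp_dynes_cm2`); unit handling follows the column suffix.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the header).
#' @return A measurement data.frame as from [flow_measurements()].
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  flow_col <- intersect(c("flow_ml_min", "flow_cm3_s"), names(raw))
  dp_col <- intersect(c("dp_mmHg", "dp_dynes_cm2"), names(raw))
  if (length(flow_col) == 0L || length(dp_col) == 0L) {
    stop("expected columns flow_ml_min|flow_cm3_s and dp_mmHg|dp_dynes_cm2 in ",
         path, call. = FALSE)
  }
  flow_measurements(
    flow = raw[[flow_col[1]]],
    pressure_drop = raw[[dp_col[1]]],
    chamber = if ("chamber" %in% names(raw)) raw$chamber else "chamber",
    flow_unit = if (flow_col[1] == "flow_ml_min") "mL/min" else "cm3/s",
    pressure_unit = if (dp_col[1] == "dp_mmHg") "mmHg" else "dynes/cm2"
  )
}

#' Estimate chamber hydraulic resistance from a flow sweep
#'
#' Per measurement point the resistance is `dP / Q`; the headline
#' `mean_resistance` is the arithmetic mean of the per-point values and
#' `slope_resistance` is the through-origin least-squares slope
#' `sum(dP*Q)/sum(Q^2)`. For noiseless linear data the two coincide with the
#' true resistance exactly. The computation is deterministic: the same input
#' reproduces the same result bit for bit.
#'
#' @param measurements A data.frame from [flow_measurements()] or
#'   [read_measurements()] (columns `flow_cm3_s`, `dp_dynes_cm2`, optionally
#'   `chamber`). If several chambers are present, each is characterized
#'   separately.
#' @return For a single chamber, an object of class `chamber_characterization`:
#'   a list with `chamber`, `per_point` (data.frame of flow and resistance),
#'   `mean_resistance`, `slope_resistance`, `n_points`. For several chambers,
#'   a named list of such objects.
#' @examples
#' m <- flow_measurements(c(1.33, 2.0, 2.67), 1671 * c(1.33, 2.0, 2.67))
#' characterize(m)$mean_resistance    # 1671
#' @export
characterize <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("flow_cm3_s", "dp_dynes_cm2") %in% names(measurements)))
  if (nrow(measurements) == 0L) stop("no measurements supplied", call. = FALSE)
  bad <- which(measurements$flow_cm3_s <= 0)
  if (length(bad)) {
    stop("non-positive flow at measurement index ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chambers <- unique(measurements$chamber %||% "chamber")
  if (is.null(measurements$chamber)) measurements$chamber <- "chamber"
  one <- function(ch) {
    m <- measurements[measurements$chamber == ch, , drop = FALSE]
    r <- m$dp_dynes_cm2 / m$flow_cm3_s
    structure(list(
      chamber = ch,
      per_point = data.frame(flow_cm3_s = m$flow_cm3_s,
                             dp_dynes_cm2 = m$dp_dynes_cm2,
                             resistance = r),
      mean_resistance = mean(r),
      slope_resistance = sum(m$dp_dynes_cm2 * m$flow_cm3_s) / sum(m$flow_cm3_s^2),
      n_points = nrow(m)
    ), class = "chamber_characterization")
  }
  if (length(chambers) == 1L) one(chambers) else {
    out <- lapply(chambers, one)
    names(out) <- chambers
    out
  }
}

#' @export
print.chamber_characterization <- function(x, ...) {
  cat(sprintf("Chamber %s: mean resistance %.0f, slope resistance %.0f dynes.s/cm5 (n = %d)\n",
              x$chamber, x$mean_resistance, x$slope_resistance, x$n_points))
  invisible(x)
}

# percentages are reported rounded half-up to 2 decimals (commercial rounding,
# matching the bench reports); base round() is banker's rounding
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Chamber resistance as a percentage of coronary resistance
#'
#' `100 * chamber / coronary`, rounded half-up to two decimals. Used to show
#' that the chamber's intrinsic resistance is negligible next to the
#' capillary-bed resistance it sits in series with.
#'
#' @param chamber_resistance Chamber resistance, dynes.s/cm5 (>= 0). Vectorized.
#' @param coronary_resistance Coronary distal resistance, dynes.s/cm5 (> 0).
#' @param round Round half-up to 2 decimals (default TRUE).
#' @return Percentage(s).
#' @examples
#' percent_of_coronary(1671, 254250)   # 0.66
#' @export
percent_of_coronary <- function(chamber_resistance, coronary_resistance,
                                round = TRUE) {
  stopifnot(is.numeric(chamber_resistance), is.numeric(coronary_resistance))
  if (any(coronary_resistance <= 0)) {
    stop("coronary_resistance must be > 0", call. = FALSE)
  }
  if (any(chamber_resistance < 0)) {
    stop("chamber_resistance must be >= 0", call. = FALSE)
  }
  pct <- 100 * chamber_resistance / coronary_resistance
  if (round) round_half_up(pct, 2) else pct
}

#' Percent-of-coronary report table
#'
#' Tabulates chamber resistance as a percentage of each vessel's coronary
#' resistance at rest (R), light exercise (E1) and moderate exercise (E2).
#' Accepts either one mean resistance per chamber (one row per vessel) or
#' per-flow resistances (one row per vessel x flow setpoint).
#'
#' @param chamber_resistance Either a named numeric vector of mean
#'   resistances (names = vessels, e.g. `c(LAD = 1671, ...)`), or a
#'   data.frame with columns `chamber`, `flow_cm3_s`, `resistance` for the
#'   per-flow form.
#' @param presets Activity presets as from [activity_presets()].
#' @return A data.frame with columns `vessel`, (optionally `flow_cm3_s`,)
#'   `R`, `E1`, `E2` — percentages rounded half-up to 2 decimals.
#' @examples
#' percent_table(c(LAD = 1671, LCX = 1820, RCA = 591))
#' @export
percent_table <- function(chamber_resistance, presets = activity_presets()) {
  .check_presets(presets)
  cols <- c(rest = "R", light_exercise = "E1", moderate_exercise = "E2")
  if (is.data.frame(chamber_resistance)) {
    stopifnot(all(c("chamber", "flow_cm3_s", "resistance")
                  %in% names(chamber_resistance)))
    df <- chamber_resistance
    base <- data.frame(vessel = df$chamber, flow_cm3_s = df$flow_cm3_s,
                       stringsAsFactors = FALSE)
    res <- df$resistance
  } else {
    stopifnot(is.numeric(chamber_resistance), !is.null(names(chamber_resistance)))
    base <- data.frame(vessel = names(chamber_resistance),
                       stringsAsFactors = FALSE)
    res <- unname(chamber_resistance)
  }
  unknown <- setdiff(unique(base$vessel), unique(presets$vessel))
  if (length(unknown)) {
    stop("no presets for vessel(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (a in names(cols)) {
    coronary <- vapply(base$vessel, function(v) .preset_resistance(presets, v, a),
                       numeric(1))
    base[[cols[[a]]]] <- percent_of_coronary(res, coronary)
  }
  rownames(base) <- NULL
  base
}
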