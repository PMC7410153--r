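## Lumped-parameter (0D) model of the phantom flow circuit: an aortic inlet
## feeding parallel branches, each a series chain of (optional) epicardial
## artery resistance, a compliance chamber (series resistance R_ch plus a
## capacitance C to ground at the chamber node), and a distal-resistance
## catheter to an atmospheric outlet.  The hydraulic/electrical analogy is
## exact: pressure ~ voltage, flow ~ current, R = dP/Q.

#' Branch of the phantom network
#'
#' One coronary tree: artery resistance upstream of the chamber node,
#' chamber resistance + catheter resistance downstream of it, and an
#' optional chamber compliance for transient simulation.
#'
#' @param vessel Branch label, typically `"LAD"`, `"LCX"` or `"RCA"`.
#' @param chamber_resistance Chamber series resistance, dynes.s/cm5 (>= 0).
#' @param catheter_resistance Distal catheter resistance, dynes.s/cm5 (>= 0).
#' @param artery_resistance Epicardial artery resistance, dynes.s/cm5
#'   (default 0: the 3D-printed artery's resistance is negligible next to
#'   the distal elements).
#' @param chamber_compliance Chamber compliance in cm5/dyne; required (> 0)
#'   only for transient simulation.
#' @param outlet_pressure Outlet reference pressure, dynes/cm2 (default 0,
#'   atmospheric).
#' @return An object of class `branch_model`.
#' @examples
#' branch_model("LAD", chamber_resistance = 1671, catheter_resistance = 252579)
#' @export
branch_model <- function(vessel, chamber_resistance, catheter_resistance,
                         artery_resistance = 0, chamber_compliance = NULL,
                         outlet_pressure = 0) {
  stopifnot(is.character(vessel), length(vessel) == 1L)
  r <- c(artery_resistance, chamber_resistance, catheter_resistance)
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("branch resistances must be finite and >= 0", call. = FALSE)
  }
  if (sum(r) <= 0) stop("total series resistance must be > 0", call. = FALSE)
  if (!is.null(chamber_compliance) && chamber_compliance <= 0) {
    stop("chamber_compliance must be > 0 when supplied", call. = FALSE)
  }
  structure(list(vessel = vessel,
                 artery_resistance = artery_resistance,
                 chamber_resistance = chamber_resistance,
                 catheter_resistance = catheter_resistance,
                 chamber_compliance = chamber_compliance,
                 outlet_pressure = outlet_pressure),
            class = "branch_model")
}

.branch_series_resistance <- function(b) {
  b$artery_resistance + b$chamber_resistance + b$catheter_resistance
}

# resistance downstream of the compliance node (chamber + catheter)
.branch_distal_resistance <- function(b) {
  b$chamber_resistance + b$catheter_resistance
}

#' Phantom flow network
#'
#' The full circuit: an inlet driven either by a pressure source (set
#' `inlet_pressure`) or a flow source (set `inlet_flow`), a list of parallel
#' branches, and an optional aortic outflow path to atmosphere modelling the
#' distal aorta.
#'
#' @param branches A list of [branch_model()] objects (>= 1).
#' @param inlet_pressure Inlet pressure, dynes/cm2 (pressure-driven mode).
#' @param inlet_flow Inlet flow, cm3/s (flow-driven mode). Exactly one of
#'   `inlet_pressure`/`inlet_flow` must be given.
#' @param aortic_outlet_resistance Optional resistance of the aortic outflow
#'   path to atmosphere, dynes.s/cm5 (> 0 if given).
#' @return An object of class `phantom_network`.
#' @examples
#' net <- phantom_network(
#'   list(branch_model("LAD", 1671, 252579)),
#'   inlet_pressure = convert_pressure(100, "mmHg", "dynes/cm2")
#' )
#' @export
phantom_network <- function(branches, inlet_pressure = NULL, inlet_flow = NULL,
                            aortic_outlet_resistance = NULL) {
  if (inherits(branches, "branch_model")) branches <- list(branches)
  stopifnot(is.list(branches), length(branches) >= 1L,
            all(vapply(branches, inherits, logical(1), "branch_model")))
  if (is.null(inlet_pressure) == is.null(inlet_flow)) {
    stop("give exactly one of inlet_pressure (pressure-driven) or inlet_flow (flow-driven)",
         call. = FALSE)
  }
  if (!is.null(aortic_outlet_resistance) && aortic_outlet_resistance <= 0) {
    stop("aortic_outlet_resistance must be > 0 when supplied", call. = FALSE)
  }
  labels <- vapply(branches, `[[`, character(1), "vessel")
  if (anyDuplicated(labels)) stop("branch vessel labels must be unique", call. = FALSE)
  names(branches) <- labels
  structure(list(branches = branches,
                 inlet_pressure = inlet_pressure,
                 inlet_flow = inlet_flow,
                 aortic_outlet_resistance = aortic_outlet_resistance),
            class = "phantom_network")
}

#' Steady-state solution of the phantom circuit
#'
#' Pressure-driven mode applies the hydraulic Ohm law per branch,
#' `Q = (P_in - P_out) / R_series`; flow-driven mode first solves the inlet
#' pressure so that branch (plus aortic-outlet) flows sum to the source
#' flow. Compliances carry no flow at steady state and are ignored. Flow is
#' conserved at the inlet node to numerical precision.
#'
#' @param network A [phantom_network()].
#' @return An object of class `steady_state_solution`: a list with
#'   `inlet_pressure`, `inlet_flow`, `aortic_outlet_flow`, and `branches`, a
#'   data.frame with per-branch flow and node pressures (after the artery
#'   segment and after the chamber).
#' @examples
#' net <- phantom_network(
#'   list(branch_model("LAD", 1671, 252579),
#'        branch_model("LCX", 1820, 135180),
#'        branch_model("RCA",  591, 478409)),
#'   inlet_pressure = convert_pressure(100, "mmHg", "dynes/cm2")
#' )
#' solve_steady_state(net)
#' @export
solve_steady_state <- function(network) {
  stopifnot(inherits(network, "phantom_network"))
  br <- network$branches
  r_series <- vapply(br, .branch_series_resistance, numeric(1))
  p_out <- vapply(br, `[[`, numeric(1), "outlet_pressure")
  if (any(r_series <= 0)) {
    stop("every branch needs total series resistance > 0", call. = FALSE)
  }

  if (!is.null(network$inlet_pressure)) {
    p_in <- network$inlet_pressure
  } else {
    # flow source: P_in from nodal balance at the inlet
    g <- 1 / r_series
    g_ao <- if (is.null(network$aortic_outlet_resistance)) 0 else
      1 / network$aortic_outlet_resistance
    p_in <- (network$inlet_flow + sum(g * p_out)) / (sum(g) + g_ao)
  }

  q <- (p_in - p_out) / r_series
  q_ao <- if (is.null(network$aortic_outlet_resistance)) 0 else
    p_in / network$aortic_outlet_resistance

  branches <- data.frame(
    vessel = names(br),
    flow_cm3_s = q,
    p_after_artery = p_in - q * vapply(br, `[[`, numeric(1), "artery_resistance"),
    p_after_chamber = p_in - q * (vapply(br, `[[`, numeric(1), "artery_resistance") +
                                    vapply(br, `[[`, numeric(1), "chamber_resistance")),
    outlet_pressure = p_out,
    stringsAsFactors = FALSE
  )
  rownames(branches) <- NULL
  structure(list(inlet_pressure = p_in,
                 inlet_flow = sum(q) + q_ao,
                 aortic_outlet_flow = q_ao,
                 branches = branches),
            class = "steady_state_solution")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat(sprintf("Steady state: inlet %.1f mmHg, total flow %.3f cm3/s (%.1f mL/min)\n",
              convert_pressure(x$inlet_pressure, "dynes/cm2", "mmHg"),
              x$inlet_flow, convert_flow(x$inlet_flow, "cm3/s", "mL/min")))
  b <- x$branches
  b$flow_ml_min <- convert_flow(b$flow_cm3_s, "cm3/s", "mL/min")
  print(b[, c("vessel", "flow_cm3_s", "flow_ml_min")], digits = 4, ...)
  invisible(x)
}

#' Transient (RC) simulation of the phantom circuit
#'
#' Integrates one first-order compartment per branch,
#' `C_i dP_i/dt = Q_in,i - (P_i - P_out,i) / R_distal,i`, where `P_i` is the
#' chamber pressure and `R_distal,i` the chamber-plus-catheter resistance.
#' Flow-driven networks place an ideal check valve at the inlet (the ball
#' valve standing in for the aortic valve): negative source flow is clipped
#' to zero, after which the inlet node pressure follows from the branch
#' balance. With more than one branch, or in pressure-driven mode, every
#' branch needs `artery_resistance > 0` so the split of inflow is defined.
#'
#' The integrator is classical fixed-step RK4; the step must satisfy
#' `dt < 2 * min(R_distal * C) / safety_factor` (default safety factor 5),
#' comfortably inside the explicit stability region and small enough that
#' the O(dt^4) error is negligible against the analytic solutions used to
#' validate it.
#'
#' @param network A [phantom_network()]; all branches need
#'   `chamber_compliance` set.
#' @param inflow A function of time (s) returning inlet flow in cm3/s
#'   (flow-driven mode; defaults to the network's constant `inlet_flow`).
#'   Ignored in pressure-driven mode.
#' @param duration Simulated time, s.
#' @param dt Time step, s.
#' @param p0 Initial chamber pressures, dynes/cm2 (recycled; default 0).
#' @param safety_factor Stability safety factor (>= 1).
#' @return An object of class `transient_solution`: a data.frame with
#'   `time_s`, `inlet_flow`, `inlet_pressure`, and per-branch
#'   `p_<vessel>` (chamber pressure, dynes/cm2) and `q_<vessel>` (branch
#'   outflow, cm3/s) columns.
#' @examples
#' net <- phantom_network(
#'   list(branch_model("LAD", 1671, 252579, chamber_compliance = 1e-4)),
#'   inlet_flow = 1.0
#' )
#' sim <- simulate_transient(net, duration = 300, dt = 0.5)
#' tail(sim, 1)
#' @export
simulate_transient <- function(network, inflow = NULL, duration, dt,
                               p0 = 0, safety_factor = 5) {
  stopifnot(inherits(network, "phantom_network"),
            is.numeric(duration), is.numeric(dt), dt > 0, dt < duration,
            safety_factor >= 1)
  br <- network$branches
  nb <- length(br)
  comp <- vapply(br, function(b) b$chamber_compliance %||% NA_real_, numeric(1))
  if (any(is.na(comp))) {
    stop("transient simulation needs chamber_compliance on every branch",
         call. = FALSE)
  }
  r_dist <- vapply(br, .branch_distal_resistance, numeric(1))
  r_art <- vapply(br, `[[`, numeric(1), "artery_resistance")
  p_out <- vapply(br, `[[`, numeric(1), "outlet_pressure")
  if (any(r_dist <= 0)) stop("chamber + catheter resistance must be > 0", call. = FALSE)

  tau_min <- min(r_dist * comp)
  if (dt >= 2 * tau_min / safety_factor) {
    stop(sprintf("dt = %g s too large for stability: need dt < %g s (2*min(RC)/safety_factor)",
                 dt, 2 * tau_min / safety_factor), call. = FALSE)
  }

  pressure_driven <- !is.null(network$inlet_pressure)
  if (pressure_driven) {
    if (any(r_art <= 0)) {
      stop("pressure-driven transients need artery_resistance > 0 on every branch",
           call. = FALSE)
    }
  } else {
    if (is.null(inflow)) {
      q0 <- network$inlet_flow
      inflow <- function(t) rep_len(q0, length(t))
    }
    if (nb > 1L && any(r_art <= 0)) {
      stop("flow-driven transients with several branches need artery_resistance > 0 ",
           "to define the flow split", call. = FALSE)
    }
  }
  g_ao <- if (is.null(network$aortic_outlet_resistance)) 0 else
    1 / network$aortic_outlet_resistance

  # inlet node pressure and per-branch inflow for a given chamber state
  inlet_state <- function(p, t) {
    if (pressure_driven) {
      p_in <- network$inlet_pressure
      q_in <- (p_in - p) / r_art
    } else {
      q_raw <- inflow(t)
      if (!is.finite(q_raw)) {
        stop("inflow waveform returned a non-finite value at t = ", t,
             call. = FALSE)
      }
      q_src <- max(q_raw, 0)              # ideal check valve at the inlet
      if (nb == 1L && r_art[1] == 0) {
        q_in <- q_src
        p_in <- p[1]
      } else {
        g <- 1 / r_art
        p_in <- (q_src + sum(g * p)) / (sum(g) + g_ao)
        q_in <- g * (p_in - p)
      }
    }
    list(p_in = p_in, q_in = q_in)
  }
  deriv <- function(p, t) {
    st <- inlet_state(p, t)
    (st$q_in - (p - p_out) / r_dist) / comp
  }

  n_steps <- floor(duration / dt + 1e-9)
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  p <- rep_len(p0, nb)
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 2L + 2L * nb)
  record <- function(i, p, t) {
    st <- inlet_state(p, t)
    out[i, ] <<- c(sum(st$q_in), st$p_in, p, (p - p_out) / r_dist)
  }
  record(1L, p, times[1])
  for (i in seq_len(n_steps)) {
    t <- times[i]
    k1 <- deriv(p, t)
    k2 <- deriv(p + dt / 2 * k1, t + dt / 2)
    k3 <- deriv(p + dt / 2 * k2, t + dt / 2)
    k4 <- deriv(p + dt * k3, t + dt)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    record(i + 1L, p, times[i + 1L])
  }
  labels <- names(br)
  res <- data.frame(time_s = times, inlet_flow = out[, 1], inlet_pressure = out[, 2])
  for (j in seq_len(nb)) {
    res[[paste0("p_", labels[j])]] <- out[, 2L + j]
    res[[paste0("q_", labels[j])]] <- out[, 2L + nb + j]
  }
  class(res) <- c("transient_solution", "data.frame")
  res
}

#' Read a phantom network from a YAML or JSON config file
#'
#' Schema: a top-level `inlet` block with exactly one of `pressure_mmHg`,
#' `pressure_dynes_cm2`, `flow_ml_min`, `flow_cm3_s`; a `branches` list of
#' entries with `vessel`, `chamber_resistance`, `catheter_resistance`, and
#' optional `artery_resistance`, `chamber_compliance`, `outlet_pressure`;
#' optional top-level `aortic_outlet_resistance`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [phantom_network()].
#' @export
read_network_config <- function(path) {
  cfg <- .read_config(path)
  if (is.null(cfg$inlet) || is.null(cfg$branches)) {
    stop("network config needs 'inlet' and 'branches' keys: ", path, call. = FALSE)
  }
  inl <- cfg$inlet
  p_in <- if (!is.null(inl$pressure_mmHg))
    convert_pressure(inl$pressure_mmHg, "mmHg", "dynes/cm2") else
    inl$pressure_dynes_cm2
  q_in <- if (!is.null(inl$flow_ml_min))
    convert_flow(inl$flow_ml_min, "mL/min", "cm3/s") else inl$flow_cm3_s
  branches <- lapply(cfg$branches, function(b) {
    branch_model(vessel = b$vessel,
                 chamber_resistance = b$chamber_resistance,
                 catheter_resistance = b$catheter_resistance %||% 0,
                 artery_resistance = b$artery_resistance %||% 0,
                 chamber_compliance = b$chamber_compliance,
                 outlet_pressure = b$outlet_pressure %||% 0)
  })
  phantom_network(branches, inlet_pressure = p_in, inlet_flow = q_in,
                  aortic_outlet_resistance = cfg$aortic_outlet_resistance)
}

#' Configure a network for an activity state
#'
#' Replaces each branch's catheter resistance with the value that brings the
#' branch's distal resistance (chamber + catheter) to the preset for the
#' requested activity state: `preset - chamber_resistance`, realized through
#' [design_for_target()] against the catalog. The input network is not
#' modified. A warning is raised for branches whose required length falls
#' outside the catalog's feasible window (a smaller French size would be
#' needed on the bench); the resistance is still set exactly.
#'
#' @param network A [phantom_network()] whose branch labels appear in
#'   `presets$vessel`.
#' @param activity One of `"rest"`, `"light_exercise"`, `"moderate_exercise"`.
#' @param presets Activity presets, see [activity_presets()].
#' @param catalog,fluid Passed to [design_for_target()].
#' @return A new `phantom_network`; each branch gains a `catheter_design`
#'   element with the selected design row.
#' @examples
#' net <- phantom_network(
#'   list(branch_model("LAD", 1671, 1)), inlet_flow = 1
#' )
#' rest <- apply_activity(net, "rest")
#' @export
apply_activity <- function(network, activity, presets = activity_presets(),
                           catalog = catheter_catalog(),
                           fluid = fluid_properties()) {
  stopifnot(inherits(network, "phantom_network"))
  activity <- match.arg(activity, .activities)
  .check_presets(presets)
  branches <- lapply(network$branches, function(b) {
    target <- .preset_resistance(presets, b$vessel, activity)
    if (target <= b$chamber_resistance) {
      stop(sprintf("preset resistance for %s (%g) does not exceed chamber resistance (%g)",
                   b$vessel, target, b$chamber_resistance), call. = FALSE)
    }
    design <- design_for_target(target, catalog = catalog, fluid = fluid,
                                chamber_resistance = b$chamber_resistance)
    if (!any(design$feasible)) {
      warning(sprintf("no feasible catalog catheter for %s at %s (%s)",
                      b$vessel, activity, design$infeasibility_reason[1]),
              call. = FALSE)
    }
    best <- design[order(!design$feasible, abs(design$relative_error)), ][1, ]
    b$catheter_resistance <- attr(design, "corrected_target")
    b$catheter_design <- best
    b
  })
  out <- network
  out$branches <- branches
  out
}
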