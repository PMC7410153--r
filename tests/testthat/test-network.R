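rest_network <- function(inlet_pressure = convert_pressure(100, "mmHg", "dynes/cm2")) {
  phantom_network(list(
    branch_model("LAD", 1671, 252579),
    branch_model("LCX", 1820, 135180),
    branch_model("RCA",  591, 478409)
  ), inlet_pressure = inlet_pressure)
}

test_that("single-branch steady state is the hydraulic Ohm law", {
  net <- phantom_network(
    branch_model("LAD", chamber_resistance = 0, catheter_resistance = 100000),
    inlet_pressure = convert_pressure(100, "mmHg", "dynes/cm2"))
  sol <- solve_steady_state(net)
  expect_equal(sol$branches$flow_cm3_s, 133322 / 100000, tolerance = 1e-12)
})

test_that("identical parallel branches split a flow source evenly", {
  net <- phantom_network(list(
    branch_model("A", 1000, 99000),
    branch_model("B", 1000, 99000),
    branch_model("C", 1000, 99000)
  ), inlet_flow = 3)
  sol <- solve_steady_state(net)
  expect_equal(sol$branches$flow_cm3_s, rep(1, 3), tolerance = 1e-12)
  expect_equal(sol$inlet_pressure, 100000, tolerance = 1e-9)
})

test_that("rest-state phantom flows match the hand parallel-resistor solution", {
  sol <- solve_steady_state(rest_network())
  p <- 133322
  expect_equal(sol$branches$flow_cm3_s,
               c(p / 254250, p / 137000, p / 479000), tolerance = 1e-12)
  # conservation at the inlet node
  expect_equal(sol$inlet_flow, sum(sol$branches$flow_cm3_s), tolerance = 1e-12)
})

test_that("steady state matches the brute-force nodal oracle (property)", {
  set.seed(23)
  for (i in 1:10) {
    nb <- sample(1:4, 1)
    branches <- lapply(seq_len(nb), function(j) {
      branch_model(paste0("B", j),
                   artery_resistance = runif(1, 10, 5000),
                   chamber_resistance = runif(1, 100, 3000),
                   catheter_resistance = runif(1, 1e4, 5e5),
                   outlet_pressure = runif(1, 0, 5000))
    })
    r_ao <- if (runif(1) < 0.5) NULL else runif(1, 1e4, 1e6)
    net <- if (i %% 2 == 0) {
      phantom_network(branches, inlet_pressure = runif(1, 5e4, 2e5),
                      aortic_outlet_resistance = r_ao)
    } else {
      phantom_network(branches, inlet_flow = runif(1, 0.5, 5),
                      aortic_outlet_resistance = r_ao)
    }
    sol <- solve_steady_state(net)
    oracle <- nodal_solve_oracle(net)
    expect_equal(sol$branches$flow_cm3_s, unname(oracle$branch_flows),
                 tolerance = 1e-9)
    expect_equal(sol$inlet_pressure, oracle$inlet_pressure, tolerance = 1e-9)
    # conservation to 1e-9 relative in both drive modes
    expect_equal(sol$inlet_flow,
                 sum(sol$branches$flow_cm3_s) + sol$aortic_outlet_flow,
                 tolerance = 1e-9)
    if (is.null(net$inlet_pressure)) {
      expect_equal(sol$inlet_flow, net$inlet_flow, tolerance = 1e-9)
    }
  }
})

test_that("steady state is invariant under the input unit system", {
  a <- solve_steady_state(rest_network(convert_pressure(100, "mmHg", "dynes/cm2")))
  b <- solve_steady_state(rest_network(convert_pressure(13332.2, "Pa", "dynes/cm2")))
  expect_equal(a$branches$flow_cm3_s, b$branches$flow_cm3_s, tolerance = 1e-12)
})

test_that("network constructors reject ill-posed configurations", {
  expect_error(phantom_network(list(), inlet_flow = 1), "length")
  expect_error(phantom_network(branch_model("LAD", 1671, 1)), "exactly one")
  expect_error(phantom_network(branch_model("LAD", 1671, 1),
                               inlet_pressure = 1, inlet_flow = 1), "exactly one")
  expect_error(branch_model("LAD", 0, 0), "series resistance")
  expect_error(branch_model("LAD", -1, 100), "resistances")
})

test_that("constant inflow converges to the steady state with tau = RC", {
  # tau = (1671 + 252579) * 1e-4 = 25.4 s
  net <- phantom_network(
    branch_model("LAD", 1671, 252579, chamber_compliance = 1e-4),
    inlet_flow = 1.0)
  tau <- (1671 + 252579) * 1e-4
  sim <- simulate_transient(net, duration = 12 * tau, dt = tau / 100)
  p_ss <- 1.0 * (1671 + 252579)
  expect_equal(tail(sim$p_LAD, 1), p_ss, tolerance = 1e-3)
  expect_equal(tail(sim$q_LAD, 1), 1.0, tolerance = 1e-3)
  # pressure at t = tau sits at 1 - 1/e of the asymptote
  i_tau <- which.min(abs(sim$time_s - tau))
  expect_equal(sim$p_LAD[i_tau] / p_ss, 1 - exp(-1), tolerance = 1e-3)
})

test_that("a charged chamber with zero inflow decays exponentially", {
  net <- phantom_network(
    branch_model("LAD", 500, 500, chamber_compliance = 1e-4),
    inlet_flow = 0)
  tau <- 1000 * 1e-4
  p0 <- 50000
  sim <- simulate_transient(net, inflow = function(t) 0 * t,
                            duration = 3 * tau, dt = tau / 200, p0 = p0)
  i_tau <- which.min(abs(sim$time_s - tau))
  expect_equal(sim$p_LAD[i_tau] / p0, exp(-1), tolerance = 1e-6)
})

test_that("sinusoidal inflow follows the first-order low-pass response", {
  r <- 1000; c_ch <- 1e-4; tau <- r * c_ch   # 0.1 s
  net <- phantom_network(
    branch_model("LAD", 400, 600, chamber_compliance = c_ch),
    inlet_flow = 2)
  for (f in c(1, 5)) {
    w <- 2 * pi * f
    sim <- simulate_transient(
      net, inflow = function(t) 2 + 0.5 * sin(w * t),
      duration = 10 * tau + 3 / f, dt = 1e-3)
    settled <- sim[sim$time_s >= 10 * tau & sim$time_s <= 10 * tau + 3 / f, ]
    amp <- fitted_amplitude(settled$time_s, settled$p_LAD, f)
    expect_equal(amp, 0.5 * r / sqrt(1 + (w * tau)^2), tolerance = 0.02)
  }
})

test_that("the inlet check valve clips reverse source flow to zero", {
  net <- phantom_network(
    branch_model("LAD", 500, 500, chamber_compliance = 1e-4),
    inlet_flow = 0)
  sim <- simulate_transient(net, inflow = function(t) -5 + 0 * t,
                            duration = 0.2, dt = 1e-3, p0 = 10000)
  expect_true(all(sim$inlet_flow == 0))
  expect_true(all(diff(sim$p_LAD) < 0))   # pure discharge, never recharged
})

test_that("shrinking compliance drives the transient to the steady state", {
  mk <- function(c_ch) phantom_network(
    branch_model("LAD", 1671, 50000, chamber_compliance = c_ch),
    inlet_flow = 1.5)
  q_ss <- 1.5
  dev <- vapply(c(1e-4, 1e-5), function(c_ch) {
    tau_big <- 51671 * 1e-4
    sim <- simulate_transient(mk(c_ch), duration = 3 * tau_big,
                              dt = 51671 * c_ch / 50)
    abs(tail(sim$q_LAD, 1) - q_ss) / q_ss
  }, numeric(1))
  expect_lt(dev[2], dev[1] / 10)
  expect_lt(dev[2], 1e-9)
})

test_that("halving dt shrinks the integration error at fourth order", {
  net <- phantom_network(
    branch_model("LAD", 500, 500, chamber_compliance = 1e-4),
    inlet_flow = 0)
  tau <- 0.1; p0 <- 1e5
  err <- vapply(c(tau / 4, tau / 8), function(dt) {
    sim <- simulate_transient(net, inflow = function(t) 0 * t,
                              duration = tau, dt = dt, p0 = p0,
                              safety_factor = 1)
    abs(tail(sim$p_LAD, 1) - p0 * exp(-tail(sim$time_s, 1) / tau))
  }, numeric(1))
  expect_lt(err[2], err[1] / 8)   # RK4: factor ~16 expected
})

test_that("transient solver matches deSolve on a two-branch network", {
  skip_if_not_installed("deSolve")
  branches <- list(
    branch_model("LAD", 1000, 40000, artery_resistance = 2000,
                 chamber_compliance = 2e-4),
    branch_model("LCX", 1500, 60000, artery_resistance = 3000,
                 chamber_compliance = 1e-4))
  net <- phantom_network(branches, inlet_flow = 2)
  sim <- simulate_transient(net, duration = 5, dt = 1e-3)
  deriv <- function(t, p, parms) {
    g <- 1 / c(2000, 3000)
    p_in <- (2 + sum(g * p)) / sum(g)
    q_in <- g * (p_in - p)
    list((q_in - p / c(41000, 61500)) / c(2e-4, 1e-4))
  }
  ref <- deSolve::ode(y = c(0, 0), times = seq(0, 5, by = 1e-3),
                      func = deriv, parms = NULL, method = "rk4")
  expect_equal(tail(sim$p_LAD, 1), unname(tail(ref[, 2], 1)), tolerance = 1e-6)
  expect_equal(tail(sim$p_LCX, 1), unname(tail(ref[, 3], 1)), tolerance = 1e-6)
})

test_that("transient preconditions are enforced", {
  net_noc <- phantom_network(branch_model("LAD", 500, 500), inlet_flow = 1)
  expect_error(simulate_transient(net_noc, duration = 1, dt = 1e-3),
               "chamber_compliance")
  net <- phantom_network(
    branch_model("LAD", 500, 500, chamber_compliance = 1e-4), inlet_flow = 1)
  expect_error(simulate_transient(net, duration = 1, dt = 0.5), "stability")
  expect_error(simulate_transient(net, inflow = function(t) NaN * t,
                                  duration = 0.1, dt = 1e-3), "non-finite")
})

test_that("activity presets rescale catheters and reorder flows physically", {
  presets <- activity_presets()
  # non-increasing resistance with activity, per vessel
  for (v in unique(presets$vessel)) {
    r <- presets$resistance[presets$vessel == v]
    expect_true(all(diff(r[order(match(presets$activity[presets$vessel == v],
      c("rest", "light_exercise", "moderate_exercise")))]) <= 0))
  }
  base <- phantom_network(list(
    branch_model("LAD", 1671, 1),
    branch_model("LCX", 1820, 1),
    branch_model("RCA",  591, 1)
  ), inlet_pressure = 133322)
  rest <- apply_activity(base, "rest")
  mod <- apply_activity(base, "moderate_exercise")
  # the input network is untouched
  expect_equal(base$branches$LAD$catheter_resistance, 1)
  # catheter + chamber equals the preset exactly
  expect_equal(rest$branches$LAD$catheter_resistance + 1671, 254250)
  expect_equal(mod$branches$RCA$catheter_resistance + 591, 50300)
  q_rest <- solve_steady_state(rest)$branches$flow_cm3_s
  q_mod <- solve_steady_state(mod)$branches$flow_cm3_s
  expect_true(all(q_mod > q_rest))
  # zero-resistance chamber passes the preset through unchanged
  free <- phantom_network(branch_model("LAD", 0, 1), inlet_flow = 1)
  expect_equal(apply_activity(free, "rest")$branches$LAD$catheter_resistance,
               254250)
  # chamber at or above the preset is rejected
  clogged <- phantom_network(branch_model("LAD", 3e5, 1), inlet_flow = 1)
  expect_error(apply_activity(clogged, "rest"), "chamber")
})
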