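# Independent brute-force nodal solve of a phantom network, used as the
# oracle for solve_steady_state(). Builds the full conductance matrix over
# the inlet node and the two interior nodes of every branch (between artery
# and chamber, and between chamber and catheter) and solves G p = b with
# base solve(). Requires all three segment resistances > 0 so every
# conductance is finite.
nodal_solve_oracle <- function(network) {
  br <- network$branches
  nb <- length(br)
  ra <- vapply(br, `[[`, numeric(1), "artery_resistance")
  rc <- vapply(br, `[[`, numeric(1), "chamber_resistance")
  rk <- vapply(br, `[[`, numeric(1), "catheter_resistance")
  po <- vapply(br, `[[`, numeric(1), "outlet_pressure")
  stopifnot(all(ra > 0), all(rc > 0), all(rk > 0))
  ga <- 1 / ra; gc <- 1 / rc; gk <- 1 / rk

  pressure_driven <- !is.null(network$inlet_pressure)
  # unknowns: [p_in (flow-driven only)], n1_1..n1_nb, n2_1..n2_nb
  n_unknown <- 2 * nb + if (pressure_driven) 0 else 1
  G <- matrix(0, n_unknown, n_unknown)
  b <- numeric(n_unknown)
  off <- if (pressure_driven) 0 else 1
  i1 <- function(i) off + i        # node between artery and chamber
  i2 <- function(i) off + nb + i   # node between chamber and catheter

  g_ao <- if (is.null(network$aortic_outlet_resistance)) 0 else
    1 / network$aortic_outlet_resistance

  if (!pressure_driven) {
    # KCL at inlet node: sum_i ga_i (p_in - n1_i) + g_ao p_in = Q_src
    G[1, 1] <- sum(ga) + g_ao
    for (i in seq_len(nb)) G[1, i1(i)] <- -ga[i]
    b[1] <- network$inlet_flow
  }
  for (i in seq_len(nb)) {
    # KCL at n1: ga (n1 - p_in) + gc (n1 - n2) = 0
    G[i1(i), i1(i)] <- ga[i] + gc[i]
    G[i1(i), i2(i)] <- -gc[i]
    if (pressure_driven) b[i1(i)] <- ga[i] * network$inlet_pressure
    else G[i1(i), 1] <- -ga[i]
    # KCL at n2: gc (n2 - n1) + gk (n2 - p_out) = 0
    G[i2(i), i2(i)] <- gc[i] + gk[i]
    G[i2(i), i1(i)] <- -gc[i]
    b[i2(i)] <- gk[i] * po[i]
  }
  p <- solve(G, b)
  p_in <- if (pressure_driven) network$inlet_pressure else p[1]
  n1 <- p[off + seq_len(nb)]
  flows <- ga * (p_in - n1)
  list(inlet_pressure = p_in, branch_flows = flows,
       aortic_outlet_flow = g_ao * p_in)
}

# default-fluid predicted length for a reference-table row
predicted_lengths <- function(tab = reference_length_table(),
                              mu = 0.037) {
  poiseuille_length(tab$resistance, tab$radius_cm, fluid_properties(mu))
}

# least-squares amplitude of a sinusoid at known frequency
fitted_amplitude <- function(t, x, freq_hz) {
  X <- cbind(1, sin(2 * pi * freq_hz * t), cos(2 * pi * freq_hz * t))
  beta <- qr.solve(X, x)
  sqrt(beta[2]^2 + beta[3]^2)
}
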