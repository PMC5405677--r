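# Implicit circuit solver: element laws, transients, valve switching,
# periodic convergence and conservation.

test_that("element laws hold in the assembled residual", {
  # resistor R=2 between nodes pinned at 10 and 4 mmHg: branch flow 3 ml/s
  nl <- lpn_netlist(list(
    lpn_component("pressure_source", "Pa", "a", "ground", P = 10),
    lpn_component("pressure_source", "Pb", "b", "ground", P = 4),
    lpn_component("resistor", "R1", "a", "b", R = 2)
  ))
  cmp <- lpn_compile(nl, dt = 1e-3)
  st0 <- lpn_init_state(cmp)
  st1 <- lpn_step(cmp, st0)
  ia <- match("a", cmp$node_names); ib <- match("b", cmp$node_names)
  expect_equal(st1$x[ia] - st1$x[ib], 6, tolerance = 1e-12)
  flow_R1 <- (st1$x[ia] - st1$x[ib]) / 2
  expect_equal(flow_R1, 3, tolerance = 1e-12)
  r <- assemble_residual(cmp, st1, st0)
  expect_lt(max(abs(r)), 1e-10)
})

test_that("capacitor stored flow equals C * dP/dt", {
  # ramp source P = 1.5 t on a capacitor C = 2: stored flow 3 ml/s
  nl <- lpn_netlist(list(
    lpn_component("pressure_source", "ramp", "a", "ground",
                  P = function(t) 1.5 * t),
    lpn_component("capacitor", "C1", "a", "ground", C = 2)
  ))
  res <- run_to_periodic(nl, period = 0.1, dt = 1e-3, tol = Inf)
  q <- component_flow(res, "C1")
  expect_equal(unname(q[length(q)]), 3, tolerance = 1e-9)
})

test_that("RC discharge and LR step transients match closed forms", {
  # RC: R = 1, C = 1, P(0) = 1 -> P(t) = exp(-t)
  rc <- lpn_netlist(list(
    lpn_component("resistor", "R1", "n1", "ground", R = 1),
    lpn_component("capacitor", "C1", "n1", "ground", C = 1)
  ))
  cmp <- lpn_compile(rc, dt = 1e-3)
  st <- step_for(cmp, 1, lpn_init_state(cmp, P0 = 1))
  expect_lt(abs(st$x[1L] - exp(-1)), 1e-3)
  # LR: step pressure 1 into L = 1 in series with R = 1 -> Q = 1 - exp(-t)
  lr <- lpn_netlist(list(
    lpn_component("pressure_source", "P1", "n1", "ground", P = 1),
    lpn_component("inductor", "L1", "n1", "n2", L = 1),
    lpn_component("resistor", "R1", "n2", "ground", R = 1)
  ))
  cmpl <- lpn_compile(lr, dt = 1e-3)
  stl <- step_for(cmpl, 1)
  iq <- match("L1", cmpl$branch_names)
  expect_lt(abs(stl$x[cmpl$nP + iq] - (1 - exp(-1))), 1e-3)
})

test_that("invalid steps and degenerate circuits raise useful errors", {
  rc <- lpn_netlist(list(
    lpn_component("resistor", "R1", "n1", "ground", R = 1),
    lpn_component("capacitor", "C1", "n1", "ground", C = 1)
  ))
  expect_error(lpn_compile(rc, dt = 0), "positive")
  expect_error(lpn_compile(rc, dt = -1e-4), "positive")
  # a node fed only by a flow source has no unique pressure
  fl <- lpn_netlist(list(
    lpn_component("flow_source", "src", "ground", "n1", Q = 1),
    lpn_component("inductor", "L1", "n1", "n2", L = 1),
    lpn_component("flow_source", "snk", "n2", "ground", Q = 1)
  ))
  cmp <- lpn_compile(fl, dt = 1e-3)
  expect_error(lpn_step(cmp, lpn_init_state(cmp)), "singular")
})

test_that("diode valves open, close, pin flow to zero, and hold on ties", {
  mk <- function(P_up) lpn_netlist(list(
    lpn_component("pressure_source", "up", "a", "ground", P = P_up),
    lpn_component("diode_valve", "D", "a", "b", R = 0.1, L = 1e-4),
    lpn_component("resistor", "Rload", "b", "ground", R = 5),
    lpn_component("pressure_source", "dn", "b2", "ground", P = 5),
    lpn_component("resistor", "Rdn", "b", "b2", R = 0.01)
  ))
  # upstream 20 vs downstream 5: closed valve opens and conducts
  cmp <- lpn_compile(mk(20), dt = 1e-4)
  st <- step_for(cmp, 0.05)
  expect_true(st$valve_open[1L])
  expect_gt(st$x[cmp$nP + match("D", cmp$branch_names)], 0)
  # dropping the upstream pressure below downstream closes it; flow pinned 0
  cmp2 <- lpn_compile(mk(function(t) if (t < 0.05) 20 else 1), dt = 1e-4)
  st2 <- step_for(cmp2, 0.2)
  expect_false(st2$valve_open[1L])
  expect_identical(st2$x[cmp2$nP + match("D", cmp2$branch_names)], 0)
  # exactly equal pressures: a closed valve stays closed (tie-break)
  tie <- lpn_netlist(list(
    lpn_component("pressure_source", "up", "a", "ground", P = 7),
    lpn_component("diode_valve", "D", "a", "b", R = 0.1, L = 1e-4),
    lpn_component("pressure_source", "dn", "b", "ground", P = 7)
  ))
  cmp3 <- lpn_compile(tie, dt = 1e-4)
  st3 <- step_for(cmp3, 0.01)
  expect_false(st3$valve_open[1L])
})

test_that("periodic runs stop immediately with an infinite tolerance", {
  nl <- wk_with_source(windkessel_params(1, 1, 1), Q = 1)
  res <- run_to_periodic(nl, period = 0.5, dt = 1e-3, tol = Inf)
  expect_identical(res$cycles, 1L)
  expect_true(res$converged)
})

test_that("simulated input impedance matches the analytic Windkessel", {
  # multi-harmonic flow; per-harmonic agreement with Z(w) = Rp + Rd/(1+iwRdC)
  Rp <- 0.5; Rd <- 2.0; C <- 0.4; Pd <- 4; Tw <- 0.5
  amps <- c(2, 1.5, 1.0, 0.7, 0.5); phs <- c(0.3, 1.1, 2.0, 0.5, 1.7)
  Qfun <- function(t) {
    s <- 10
    for (k in 1:5) s <- s + amps[k] * cos(2 * pi * k * t / Tw + phs[k])
    s
  }
  nl <- wk_with_source(windkessel_params(Rp, Rd, C, Pd), Qfun)
  res <- run_to_periodic(nl, period = Tw, dt = 5e-5, max_cycles = 60,
                         tol = 1e-7)
  expect_true(res$converged)
  n <- nrow(res$P) - 1L
  P <- res$P[2:(n + 1L), "WK_in"]
  Q <- vapply(res$time[2:(n + 1L)], Qfun, 0)
  Ph <- stats::fft(P) / n
  Qh <- stats::fft(Q) / n
  # DC: (mean P - Pd) / mean Q = Rp + Rd
  expect_lt(abs((Re(Ph[1L]) - Pd) / Re(Qh[1L]) - (Rp + Rd)) / (Rp + Rd),
            0.01)
  for (k in 1:5) {
    Z_sim <- Ph[k + 1L] / Qh[k + 1L]
    Z_an <- Rp + Rd / (1 + 1i * 2 * pi * k / Tw * Rd * C)
    expect_lt(Mod(Z_sim - Z_an) / Mod(Z_an), 0.01)
  }
})

test_that("the closed patient loop conserves flow, volume and valve direction", {
  cfg <- patient_config("baseline", dt = 5e-4, max_cycles = 60, tol = 1e-3)
  res <- run_model(cfg)
  expect_true(res$converged)
  cons <- check_conservation(res)
  expect_lt(cons$max_kcl_residual, 1e-6)
  expect_lt(abs(cons$volume_drift_per_cycle), 1e-3)
  expect_gte(min(res$Q[, c("NAV", "RA_valve")]), -1e-9)
  # warm restart continues from the stored state without a transient
  res2 <- run_to_periodic(config_netlist(cfg), period = cfg$period,
                          dt = cfg$dt, max_cycles = 3, tol = 1e-3,
                          init = res$final_state)
  expect_true(res2$converged)
})
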