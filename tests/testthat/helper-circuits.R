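# Shared fixtures: small circuits and comparison helpers.

# Windkessel driven by a constant or functional flow source.
wk_with_source <- function(params, Q) {
  lpn_netlist(c(
    list(lpn_component("flow_source", "src", "ground", "WK_in", Q = Q)),
    list(make_windkessel("WK", params))
  ))
}

# Integrate a compiled circuit for a fixed duration, returning the state.
step_for <- function(compiled, duration, state = lpn_init_state(compiled)) {
  n <- round(duration / compiled$dt)
  for (i in seq_len(n)) state <- lpn_step(compiled, state)
  state
}

expect_netlist_equal <- function(a, b) {
  expect_equal(length(a$components), length(b$components))
  expect_identical(a$ref, b$ref)
  for (i in seq_along(a$components)) {
    ca <- a$components[[i]]; cb <- b$components[[i]]
    expect_identical(ca$kind, cb$kind)
    expect_identical(ca$name, cb$name)
    expect_identical(ca$node_from, cb$node_from)
    expect_identical(ca$node_to, cb$node_to)
    expect_equal(ca$parameters, cb$parameters, tolerance = 0)
  }
}

# Discrete C1 diagnostic: the largest jump of the discrete derivative over
# the (circular) grid, compared with the curvature bound of an n-harmonic
# band-limited signal. A C0 kink violates the bound regardless of dt.
max_slope_jump <- function(E, period) {
  n <- length(E)
  dt <- period / n
  dE <- (E[c(2:n, 1L)] - E) / dt
  max(abs(dE[c(2:n, 1L)] - dE))
}
c1_bound <- function(E, period, n_harmonics = 10) {
  dt <- period / length(E)
  (2 * pi * n_harmonics / period)^2 * max(abs(E)) * dt * 1.1
}

# Deterministic coarse solver settings used by simulation-heavy tests.
coarse_cfg <- function(model, ...) {
  patient_config(model, dt = 1e-3, max_cycles = 200, tol = 1e-5, ...)
}
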