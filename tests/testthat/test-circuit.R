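# Circuit data model: components, Windkessel builders, patient netlist.

test_that("component constructors enforce their invariants", {
  expect_error(lpn_component("resistor", "R1", "a", "a", R = 1), "differ")
  expect_error(lpn_component("resistor", "R1", "a", "b", R = 0), "positive")
  expect_error(lpn_component("resistor", "R1", "a", "b", R = -2), "positive")
  expect_error(lpn_component("capacitor", "C1", "a", "b"), "positive")
  expect_error(lpn_component("diode_valve", "D1", "a", "b", R = 1), "'L'")
  expect_error(lpn_component("resistor", "", "a", "b", R = 1), "non-empty")
  expect_no_error(lpn_component("elastance_chamber", "v", "a", "ground",
                                E = list(E_min = 1), V_init = 10))
  d <- lpn_component("diode_valve", "D1", "a", "b", R = 1e-3, L = 1e-5)
  expect_identical(d$kind, "diode_valve")
  expect_equal(d$parameters$L, 1e-5)
})

test_that("make_windkessel builds the Rp + (Rd || C) subcircuit", {
  p <- windkessel_params(Rp = 3.277e-2, Rd = 0.1361, C = 1.76235)
  open <- make_windkessel("RPA", p, closed_loop = TRUE)
  expect_length(open, 3L)
  expect_setequal(vapply(open, `[[`, "", "kind"),
                  c("resistor", "capacitor", "resistor"))
  # distal node left open: no pressure source
  closed <- make_windkessel("RPA", p, closed_loop = FALSE)
  expect_length(closed, 4L)
  expect_identical(closed[[4L]]$kind, "pressure_source")
  expect_error(windkessel_params(0, 1, 1), "positive")
})

test_that("stand-alone Windkessel reaches Pd + (Rp+Rd)*Q at steady state", {
  cases <- list(list(p = windkessel_params(1, 1, 1, Pd = 0), Q = 1,
                     expected = 2),
                list(p = windkessel_params(0.5, 2.5, 0.75, Pd = 5), Q = 2,
                     expected = 11))
  for (cs in cases) {
    nl <- wk_with_source(cs$p, cs$Q)
    cmp <- lpn_compile(nl, dt = 2e-3)
    st <- step_for(cmp, 10 * cs$p$Rd * cs$p$C,
                   lpn_init_state(cmp, P0 = cs$p$Pd))
    P_in <- st$x[match("WK_in", cmp$node_names)]
    expect_lt(abs(P_in - cs$expected) / cs$expected, 1e-3)
  }
})

test_that("the patient netlist carries every packaged table entry exactly once", {
  nl <- build_patient_circuit()
  tabs <- default_parameter_tables()
  pull <- function(name, key) {
    hits <- Filter(function(cp) cp$name == name, nl$components)
    expect_length(hits, 1L)
    hits[[1L]]$parameters[[key]]
  }
  for (o in names(tabs$windkessel_outlets)) {
    w <- tabs$windkessel_outlets[[o]]
    expect_identical(pull(paste0(o, "_Rp"), "R"), w$Rp)
    expect_identical(pull(paste0(o, "_Rd"), "R"), w$Rd)
    expect_identical(pull(paste0(o, "_C"), "C"), w$C)
  }
  for (v in names(tabs$venous_sections)) {
    w <- tabs$venous_sections[[v]]
    expect_identical(pull(paste0(v, "_Rp"), "R"), w$Rp)
    expect_identical(pull(paste0(v, "_Rd"), "R"), w$Rd)
    expect_identical(pull(paste0(v, "_C"), "C"), w$C)
  }
  h <- tabs$heart_and_shunts
  expect_identical(pull("RA_valve", "R"), h[["RA_valve_R"]])
  expect_identical(pull("RA_valve", "L"), h[["RA_valve_L"]])
  expect_identical(pull("NAV", "R"), h[["NAV_R"]])
  expect_identical(pull("NAV", "L"), h[["NAV_L"]])
  expect_identical(pull("Collateral1", "R"), h[["Collateral1"]])
  expect_identical(pull("Collateral2", "R"), h[["Collateral2"]])
  expect_identical(pull("ASD", "R"), h[["ASD"]])
})

test_that("incomplete tables are rejected and builds are deterministic", {
  tabs <- default_parameter_tables()
  tabs$heart_and_shunts <-
    tabs$heart_and_shunts[names(tabs$heart_and_shunts) != "Collateral2"]
  expect_error(build_patient_circuit(tables = tabs), "Collateral2")
  tabs2 <- default_parameter_tables()
  tabs2$windkessel_outlets$LPA <- NULL
  expect_error(build_patient_circuit(tables = tabs2), "LPA")
  a <- build_patient_circuit()
  b <- build_patient_circuit()
  expect_netlist_equal(a, b)
})

test_that("validate_netlist names the offending node or component", {
  nl <- build_patient_circuit()
  expect_silent(validate_netlist(nl))
  # isolated node
  bad <- lpn_netlist(list(
    lpn_component("resistor", "R1", "a", "ground", R = 1),
    lpn_component("resistor", "R2", "b", "c", R = 1)
  ), validate = FALSE)
  expect_error(validate_netlist(bad), "b, c")
  # duplicate component names
  dup <- lpn_netlist(list(
    lpn_component("resistor", "R1", "a", "ground", R = 1),
    lpn_component("resistor", "R1", "a", "ground", R = 2)
  ), validate = FALSE)
  expect_error(validate_netlist(dup), "duplicate.*R1")
  # non-positive parameter smuggled past the constructor
  hacked <- lpn_netlist(list(
    lpn_component("resistor", "R1", "a", "ground", R = 1)
  ), validate = FALSE)
  hacked$components[[1L]]$parameters$R <- 0
  expect_error(validate_netlist(hacked), "non-positive")
})

test_that("netlist text format round-trips component by component", {
  nl <- build_patient_circuit()
  path <- withr::local_tempfile(fileext = ".net")
  write_netlist(nl, path)
  back <- read_netlist(path)
  expect_netlist_equal(nl, back)
})
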