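# Packaged parameter set for the reference single-ventricle patient model.
# Units: mmHg, ml/s, ml, s (resistance mmHg*s/ml, compliance ml/mmHg,
# inertance mmHg*s^2/ml).

#' Reference circulation parameter tables
#'
#' The packaged parameter set of the reference Blalock-Taussig shunt patient
#' model: three-element Windkessel outlets for the seven arterial beds
#' (`RC`, `LC`, `RS`, `LS`, `DAo`, `RPA`, `LPA`), Windkessel-like venous
#' loop-closing sections (`SVC`, `IVC`, `RPV`, `LPV`), and the scalar heart /
#' shunt-side parameters (atrio-ventricular and neo-aortic valve open
#' resistance and inertance, two aortopulmonary collateral resistances, and
#' the atrial septal defect resistance).
#'
#' @return A list of class `parameter_tables` with elements
#'   `windkessel_outlets`, `venous_sections` (each a named list of
#'   [windkessel_params]) and `heart_and_shunts` (named numeric vector).
#' @export
default_parameter_tables <- function() {
  wk <- function(Rp, Rd, C) windkessel_params(Rp, Rd, C)
  tabs <- list(
    windkessel_outlets = list(
      RC  = wk(0.50931, 2.68885, 0.71603),
      LC  = wk(0.50004, 2.43319, 0.74383),
      RS  = wk(0.50878, 2.6307, 0.74512),
      LS  = wk(0.45264, 2.10615, 0.84197),
      DAo = wk(5.919e-2, 0.28437, 5.01933),
      RPA = wk(3.277e-2, 0.1361, 1.76235),
      LPA = wk(3.108e-2, 0.31950, 1.00099)
    ),
    venous_sections = list(
      SVC = wk(0.15500, 1.807e-2, 284.73779),
      IVC = wk(0.22075, 2.261e-2, 135.95630),
      RPV = wk(2.693e-2, 2.040e-2, 72.05470),
      LPV = wk(1.027e-2, 8.970e-3, 132.96730)
    ),
    heart_and_shunts = c(
      RA_valve_R  = 3.3e-3,
      RA_valve_L  = 6.667e-5,
      NAV_R       = 1.0e-3,
      NAV_L       = 1.0e-5,
      Collateral1 = 9.69600e-2,
      Collateral2 = 0.05,
      ASD         = 3.0e-4
    )
  )
  structure(tabs, class = "parameter_tables")
}

REQUIRED_OUTLETS <- c("RC", "LC", "RS", "LS", "DAo", "RPA", "LPA")
REQUIRED_VENOUS <- c("SVC", "IVC", "RPV", "LPV")
REQUIRED_HEART <- c("RA_valve_R", "RA_valve_L", "NAV_R", "NAV_L",
                    "Collateral1", "Collateral2", "ASD")

check_parameter_tables <- function(tables) {
  miss <- setdiff(REQUIRED_OUTLETS, names(tables$windkessel_outlets))
  if (length(miss))
    stop("parameter tables missing Windkessel outlet(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(REQUIRED_VENOUS, names(tables$venous_sections))
  if (length(miss))
    stop("parameter tables missing venous section(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(REQUIRED_HEART, names(tables$heart_and_shunts))
  if (length(miss))
    stop("parameter tables missing heart/shunt value(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Heart-side specification for the patient circuit
#'
#' Parameters of the 0D heart compartments: the time-varying-elastance single
#' ventricle and two constant-compliance atria. The atrial compliances are
#' modelling assumptions (no measured values exist for the reference patient).
#'
#' @param elastance Ventricular elastance: a function of time (s) returning
#'   mmHg/ml, an [elastance_curve], or a named list of Gaussian parameters
#'   (`E_min`, `E_max`, `t0`, `sigma`, `period`). Default: Gaussian elastance
#'   with peak 3 mmHg/ml at 0.15 s, baseline 0.2 mmHg/ml, width 0.05 s.
#' @param V0 Ventricular unstressed volume (ml).
#' @param EDV Initial (end-diastolic) ventricular volume (ml).
#' @param C_RA,C_LA Right/left atrial compliances (ml/mmHg).
#' @param period Cardiac cycle length (s). The reference recordings do not
#'   state a heart rate; 0.46 s (about 130 bpm) is a typical 4-month-old value
#'   and is the documented default assumption.
#' @return A list of class `heart_spec`.
#' @export
heart_spec <- function(elastance = list(E_min = 0.2, E_max = 3.0, t0 = 0.15,
                                        sigma = 0.05, period = 0.46),
                       V0 = 5, EDV = 40, C_RA = 1.0, C_LA = 1.0,
                       period = 0.46) {
  stopifnot(EDV > 0, V0 >= 0, C_RA > 0, C_LA > 0, period > 0)
  structure(list(elastance = elastance, V0 = V0, EDV = EDV,
                 C_RA = C_RA, C_LA = C_LA, period = period),
            class = "heart_spec")
}

#' Build the closed-loop patient circulation netlist
#'
#' Assembles the reference single-ventricle circulation: elastance ventricle
#' -> neo-aortic diode valve -> aortic root -> resistive surrogate of the
#' image-based arterial domain (great-vessel branches, BT shunt, pulmonary
#' artery junction) -> Windkessel outlet beds -> venous loop-closing sections
#' -> atria -> atrio-ventricular diode valve -> ventricle; with an atrial
#' septal defect resistor joining the atria and two aortopulmonary collateral
#' resistors joining the systemic side to the right-lung side.
#'
#' Drainage wiring: the four head/arm beds (`RC`, `LC`, `RS`, `LS`) drain into
#' the SVC section, `DAo` into the IVC section, and the two lung beds into
#' their pulmonary-vein sections; SVC/IVC enter the right atrium and RPV/LPV
#' the left atrium.
#'
#' @param tables A `parameter_tables` list (default
#'   [default_parameter_tables()]).
#' @param surrogate A [surrogate_spec()].
#' @param heart A [heart_spec()].
#' @param collateral1_nodes,collateral2_nodes Character(2) attachment nodes
#'   for the two collateral resistors (systemic node, right-lung node). See
#'   the methods vignette for the default choice.
#' @return A validated `lpn_netlist`.
#' @export
build_patient_circuit <- function(tables = default_parameter_tables(),
                                  surrogate = surrogate_spec(),
                                  heart = heart_spec(),
                                  collateral1_nodes = c("IVC_mid", "RPV_mid"),
                                  collateral2_nodes = c("SVC_mid", "RPV_mid")) {
  check_parameter_tables(tables)
  h <- tables$heart_and_shunts
  comps <- list(
    lpn_component("elastance_chamber", "ventricle", "vent", "ground",
                  E = heart$elastance, V0 = heart$V0, V_init = heart$EDV),
    lpn_component("diode_valve", "NAV", "vent", "aoroot",
                  R = h[["NAV_R"]], L = h[["NAV_L"]]),
    lpn_component("diode_valve", "RA_valve", "ra", "vent",
                  R = h[["RA_valve_R"]], L = h[["RA_valve_L"]]),
    lpn_component("capacitor", "RA_C", "ra", "ground", C = heart$C_RA),
    lpn_component("capacitor", "LA_C", "la", "ground", C = heart$C_LA),
    lpn_component("resistor", "ASD", "la", "ra", R = h[["ASD"]]),
    build_surrogate_network(surrogate)
  )
  drain <- c(RC = "SVC_in", LC = "SVC_in", RS = "SVC_in", LS = "SVC_in",
             DAo = "IVC_in", RPA = "RPV_in", LPA = "LPV_in")
  for (o in REQUIRED_OUTLETS)
    comps <- c(comps, list(make_windkessel(o, tables$windkessel_outlets[[o]],
                                           closed_loop = TRUE,
                                           node_out = drain[[o]])))
  atrium <- c(SVC = "ra", IVC = "ra", RPV = "la", LPV = "la")
  for (v in REQUIRED_VENOUS)
    comps <- c(comps, list(make_windkessel(v, tables$venous_sections[[v]],
                                           closed_loop = TRUE,
                                           node_out = atrium[[v]])))
  comps <- c(comps, list(
    lpn_component("resistor", "Collateral1",
                  collateral1_nodes[1], collateral1_nodes[2],
                  R = h[["Collateral1"]]),
    lpn_component("resistor", "Collateral2",
                  collateral2_nodes[1], collateral2_nodes[2],
                  R = h[["Collateral2"]])
  ))
  lpn_netlist(comps, ref = "ground")
}
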