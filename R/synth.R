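# Seeded virtual-patient generator: ground-truth elastance curves, forward
# simulation of the recordings the elastance pipeline consumes, and
# synthetic clinical target tables with known ground truth.

#' Ground-truth Gaussian elastance curve
#'
#' `E(t) = E_min + (E_max - E_min) * exp(-(t - t0)^2 / (2 sigma^2))`,
#' periodized over the cycle.
#'
#' @param E_min,E_max Baseline and peak elastance (mmHg/ml,
#'   `E_max > E_min > 0`).
#' @param t0 Peak time (s); `sigma` width (s); `period` cycle length (s).
#' @param n_samples Grid size.
#' @param V0 Unstressed volume attached to the curve (ml).
#' @return An [elastance_curve]; the generating closed form is attached as
#'   attribute `"truth_fun"`.
#' @export
gen_elastance_truth <- function(E_min = 0.2, E_max = 3.0, t0 = 0.15,
                                sigma = 0.05, period = 0.46,
                                n_samples = 1024, V0 = 0) {
  f <- gaussian_elastance_function(E_min, E_max, t0, sigma, period)
  tt <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  curve <- elastance_curve(tt, f(tt), period, V0 = V0)
  attr(curve, "truth_fun") <- f
  attr(curve, "truth_params") <- list(E_min = E_min, E_max = E_max, t0 = t0,
                                      sigma = sigma, period = period)
  curve
}

#' Generate virtual-patient recordings
#'
#' Forward-simulates a single ventricle with the given ground-truth
#' elastance ejecting through a diode valve into a three-element Windkessel
#' afterload, filled from a constant-pressure preload through an inflow
#' valve. The periodic valve-flow and ventricular-pressure waveforms emulate
#' the PC-MRI flow recording and the catheter pressure trace; the measured
#' end-diastolic volume is the simulated ventricular volume at ejection
#' onset. Multiplicative Gaussian noise (seeded) is applied to the pressure
#' trace, the noisier signal in practice; flow noise is optional.
#'
#' @param truth An [elastance_curve] from [gen_elastance_truth()].
#' @param EDV Initial ventricular volume (ml); the reported EDV is measured
#'   from the converged simulation.
#' @param afterload A [windkessel_params()] (with fixed `Pd`).
#' @param preload_mmHg Constant filling pressure (mmHg).
#' @param noise_sigma Multiplicative pressure noise fraction.
#' @param flow_noise_sigma Multiplicative flow noise fraction (default 0).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param dt Simulation time step (s).
#' @param sim Optional `lpn_result` from a previous call with the same
#'   circuit inputs; re-used so that repeated noise draws do not re-simulate.
#' @return A `virtual_patient` list: `time`, `flow` (ml/s), `pressure`
#'   (mmHg, noisy), `pressure_clean`, `EDV`, `V0`, `period`, `truth`,
#'   `noise_sigma`, `seed` and the underlying `lpn_result` (`sim`).
#' @export
gen_patient_waveforms <- function(truth, EDV = 40,
                                  afterload = windkessel_params(
                                    Rp = 0.18, Rd = 1.45, C = 1.3, Pd = 2),
                                  preload_mmHg = 8,
                                  noise_sigma = 0, flow_noise_sigma = 0,
                                  seed = 1, dt = 2e-4, sim = NULL) {
  stopifnot(inherits(truth, "elastance_curve"), EDV > 0)
  res <- if (!is.null(sim)) sim else {
    nl <- lpn_netlist(list(
      lpn_component("pressure_source", "preload", "pre", "ground",
                    P = preload_mmHg),
      lpn_component("diode_valve", "inflow_valve", "pre", "vent",
                    R = 3.3e-3, L = 6.667e-5),
      lpn_component("elastance_chamber", "ventricle", "vent", "ground",
                    E = truth, V0 = truth$V0, V_init = EDV),
      lpn_component("diode_valve", "outflow_valve", "vent", "art",
                    R = 1e-3, L = 1e-5),
      make_windkessel("afterload", afterload, closed_loop = FALSE,
                      node_in = "art")
    ))
    run_to_periodic(nl, period = truth$period, dt = dt,
                    max_cycles = 40, tol = 1e-4, P0 = preload_mmHg)
  }
  sel <- seq_len(nrow(res$P) - 1L)      # one cycle, cycle-start sample first
  time <- res$time[sel]
  flow <- res$Q[sel, "outflow_valve"]
  pressure <- res$P[sel, "vent"]
  onset <- which(flow > 0.01 * max(flow))[1L]
  EDV_meas <- res$V[onset, "ventricle"]
  sv <- pracma::trapz(time, pmax(flow, 0))
  if (sv >= EDV_meas)
    stop("generated stroke volume is not smaller than EDV", call. = FALSE)
  set.seed(seed)
  noisy_p <- pressure * (1 + noise_sigma * stats::rnorm(length(pressure)))
  noisy_q <- flow * (1 + flow_noise_sigma * stats::rnorm(length(flow)))
  structure(list(seed = seed, period = truth$period, truth = truth,
                 EDV = EDV_meas, V0 = truth$V0, time = time,
                 flow = noisy_q, flow_clean = flow,
                 pressure = noisy_p, pressure_clean = pressure,
                 noise_sigma = noise_sigma, stroke_volume = sv, sim = res),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat("virtual_patient: period", x$period, "s, EDV", signif(x$EDV, 4),
      "ml, stroke volume", signif(x$stroke_volume, 4),
      "ml, pressure noise sigma", x$noise_sigma, "\n")
  invisible(x)
}

#' Synthetic clinical targets from a known simulation
#'
#' Runs a configured closed-loop model (with a known shunt state) and
#' extracts the 16-index summary as a synthetic "patient recording", with a
#' 10% relative rule on every index. Deterministic: no noise is applied.
#'
#' @param config An [patient_config()].
#' @param site_map Site map (default [default_site_map()]).
#' @param tol Relative tolerance (percent) attached to every index.
#' @param result Optional pre-computed `lpn_result` for `config`.
#' @return A list with `targets` (a `clinical_targets` table), `summary` and
#'   the `result`.
#' @export
gen_targets_from_simulation <- function(config, site_map = default_site_map(),
                                        tol = 10, result = NULL) {
  if (is.null(result)) result <- run_model(config)
  s <- summarize_hemodynamics(result, site_map)
  list(targets = clinical_targets(s$index, s$value, rule = "rel", tol = tol),
       summary = s, result = result)
}
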