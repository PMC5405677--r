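# btlpn

Closed-loop lumped-parameter (0D) hemodynamics of shunt-dependent
single-ventricle circulations.

After first-stage (Norwood) palliation for hypoplastic left heart
syndrome, a single ventricle supplies both circulations and the lungs
receive blood only through a Blalock-Taussig (BT) shunt. Two questions
matter clinically and are below the resolution of routine imaging: *how
occluded has the shunt become*, and *would an alternative shunt geometry
deliver more pulmonary flow*? `btlpn` addresses both with a desk-scale
circuit model of the whole circulation, for people who work on
cardiovascular 0D modelling, boundary-condition design for 3D
hemodynamics, or simulation-based inference from sparse clinical
recordings.

## What is inside

* **Circuit model** (`lpn_component`, `lpn_netlist`, `make_windkessel`,
  `build_patient_circuit`): netlist-defined closed loops of resistors,
  capacitors, inductors, diode valves and time-varying-elastance chambers,
  including a bundled single-ventricle patient model (three-element
  Windkessel beds, venous sections, atrial septal defect, aortopulmonary
  collaterals, BT shunt). Units: mmHg, ml/s, ml, s.
* **Implicit solver** (`run_to_periodic`, `lpn_step`,
  `check_conservation`): backward-Euler DAE stepping with diode switching,
  run to periodic steady state; conservation is verified independently of
  the solver matrices. The three-element Windkessel obeys
  `P = Pd + (Rp + Rd) Q` at steady state and
  `Z(w) = Rp + Rd / (1 + i w Rd C)` in the frequency domain, and the
  solver is tested against both.
* **Elastance pipeline** (`build_elastance`): the patient-specific
  ventricular elastance `E(t) = P(t) / (V(t) - V0)` from a valve-flow
  waveform, a ventricular pressure trace and end-diastolic volume, with
  Gaussian extrapolation of diastole, Fourier smoothing to C¹ and exact
  peak preservation.
* **Shunt surrogate and occlusion inference** (`poiseuille_resistance`,
  `effective_resistance`, `reynolds_number`, `occlusion_metrics`,
  `infer_occlusion_by_simulation`): effective shunt resistance
  `R = dP / Q`, the Hagen-Poiseuille `d^-4` diameter-scaling law, and
  bisection of the diameter scale against simulated trans-shunt targets.
* **Comparison harness** (`summarize_hemodynamics`,
  `score_against_targets`, `compare_designs`): the 16 clinical comparison
  indices, 10%-relative and pulmonary-range scoring rules, and integer
  percent-change tables between shunt designs.
* **Virtual patients** (`gen_elastance_truth`, `gen_patient_waveforms`,
  `gen_targets_from_simulation`): seeded, bit-reproducible synthetic
  recordings with known ground truth.
* **Files and CLI** (`read_netlist`, `read_config`, `cli_main`, thin
  wrapper in `inst/cli/btlpn`): text netlists, waveform CSVs, JSON
  configs/targets; `simulate`, `elastance`, `occlusion`, `compare`,
  `score`, `synth` subcommands.

## Worked example

Infer the shunt occlusion implied by catheter/MRI-derived means, then
compare the baseline shunt with a flared design:

```r
library(btlpn)

# Closed-form route: the implant-time effective resistance was
# 2.1 mmHg*s/ml; the recordings imply 41.7 mmHg across the shunt at
# 9.7 ml/s.
occlusion_from_resistances(R_ref = 2.1, gradient_mmHg = 41.7, flow_mls = 9.7)
#> occlusion_estimate (method: poiseuille_scaling)
#>   diameter scale factor: 0.836
#>   diameter reduction:    16%
#>   area occlusion:        30%
#>   resistance: 2.1 -> 4.3 mmHg*s/ml

# Closed-loop simulation of the bundled patient model
cfg  <- patient_config("baseline", dt = 1e-3, max_cycles = 200, tol = 1e-5)
base <- run_model(cfg)
base
#> lpn_result: 46 cycles of 0.46 s at dt = 0.001 s; converged
#>   final periodicity residual: 9.02e-06

flared <- run_model(patient_config("flared", dt = 1e-3, max_cycles = 200,
                                   tol = 1e-5),
                    init = base$final_state)
tab <- compare_designs(summarize_hemodynamics(base),
                       summarize_hemodynamics(flared))
tab[tab$index %in% c("LPA_pressure_mean", "shunt_flow_mean"),
    c("index", "baseline", "alternative", "change_pct_rounded")]
#>              index baseline alternative change_pct_rounded
#>  LPA_pressure_mean 10.36985    10.42074                  0
#>    shunt_flow_mean  6.89009     7.26346                  5
```

Reading the numbers: the closed-form `d^-4` estimate turns the
resistance rise 2.1 to 4.3 mmHg·s/ml into a 16% effective diameter
reduction (the simulation-based route,
`infer_occlusion_by_simulation()`, is the authoritative one - it matches
trans-shunt gradient *and* flow inside the closed loop). Replacing the
baseline shunt resistance (3.5) with the flared design's (3.3) raises
mean pulmonary pressure and shunt flow - here by about 0.05 mmHg and 5% -
the same direction the full 3D comparison reports. Absolute pressures of
the bundled model are self-consistent rather than patient-matching; the
methods vignette (`vignettes/btlpn-methods.Rmd`) explains why, along with
every modelling assumption.

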