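# Bundled reference values of the clinical case study behind the packaged
# parameter tables: recorded patient hemodynamics, the implant-time and
# occluded-shunt simulation summaries, the shunt-flaring comparison, and the
# shunt geometry / fluid properties.

#' Reference case-study values
#'
#' The numeric anchors of the reference single-ventricle BT-shunt case:
#'
#' * `patient`, `implant_time`, `occluded_baseline`, `flared`: mean aortic
#'   and pulmonary pressures (mmHg), trans-shunt gradient (mmHg), mean shunt
#'   flow (ml/s) and effective shunt resistance (mmHg*s/ml) for the recorded
#'   patient data, the implant-time-geometry simulation, the occluded
#'   baseline simulation and the flared-design simulation.
#' * `pa_comparison`: mean LPA/RPA pressure and flow of the baseline and
#'   flared designs with the published integer percent changes.
#' * `pa_pressure_range_mmHg`: the clinically reported LPA-RPA mean-pressure
#'   range used as the pulmonary acceptance rule.
#' * `shunt_geometry`: nominal diameter, effective (occluded) diameter and
#'   length (mm), the peak systolic shunt flow (mm^3/s) and blood
#'   properties.
#'
#' @return A nested list of reference values.
#' @export
reference_case <- function() {
  block <- function(pao, ppa, dp, q, r)
    list(mean_aortic_mmHg = pao, mean_pulmonary_mmHg = ppa,
         gradient_mmHg = dp, shunt_flow_mls = q, shunt_R = r)
  list(
    patient = block(56.4, 14.7, 41.7, 9.7, 4.3),
    implant_time = block(58.5, 38.6, 19.9, 9.6, 2.1),
    occluded_baseline = block(52.9, 16.0, 36.9, 10.4, 3.5),
    flared = block(52.9, 16.7, 36.2, 11.0, 3.3),
    pa_comparison = data.frame(
      index = c("LPA_pressure_mean", "RPA_pressure_mean",
                "LPA_flow_mean", "RPA_flow_mean"),
      baseline = c(16.5, 15.6, 3.6, 6.9),
      flared = c(17.6, 15.9, 3.9, 7.1),
      published_change_pct = c(7, 2, 9, 3)
    ),
    pa_totals = data.frame(
      index = c("pa_pressure_mean", "pa_flow_mean"),
      baseline = c(16.0, 10.4),
      flared = c(16.7, 11.0),
      published_change_pct = c(4, 6)
    ),
    pa_pressure_range_mmHg = c(12.9, 16.5),
    shunt_geometry = list(
      d_nominal_mm = 3.5, d_effective_mm = 2.71, length_mm = 14,
      diameter_scale = 0.78,
      peak_flow_mm3_s = 14800,
      viscosity_Pa_s = 0.004, density_g_mm3 = 0.00106
    )
  )
}
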