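# Reduced-order resistive surrogate of the image-based arterial domain:
# great-vessel branches, BT shunt and pulmonary-artery junction, plus
# Poiseuille / Reynolds utilities. Units: mmHg, ml/s, s; geometry in mm;
# viscosity Pa*s; density g/mm^3.

MMHG_PER_PA <- 1 / 133.322
SURROGATE_BRANCHES <- c("RC", "LC", "RS", "LS", "DAo")

#' Surrogate specification for the arterial domain
#'
#' The spatially resolved aorto-pulmonary domain is replaced by a resistive
#' branch network: aortic root to each great-vessel outlet entry, a shunt
#' branch from the aortic root to the pulmonary-artery junction, and two
#' junction-to-PA branches. Branch resistances default to a negligible
#' 1e-3 mmHg*s/ml (the outlet Windkessels carry the bed resistance). The
#' shunt resistance is either the empirical effective resistance (default
#' 3.5 mmHg*s/ml, the occluded-baseline value; 3.3 flared; 2.1 implant-time)
#' or derived from Hagen-Poiseuille scaling of the tube geometry.
#'
#' @param branch_R Named numeric: series resistance of the `RC`, `LC`, `RS`,
#'   `LS`, `DAo` branches (mmHg*s/ml, >= 0).
#' @param pa_branch_R Named numeric: junction-to-`LPA`/`RPA` branch
#'   resistances.
#' @param shunt_mode `"empirical"` (use `shunt_R`) or `"poiseuille"`
#'   (compute from geometry, divided by `scale^4`).
#' @param shunt_R Effective shunt resistance (mmHg*s/ml) in empirical mode.
#' @param shunt_diameter_mm,shunt_length_mm Nominal shunt geometry.
#' @param scale Diameter scale factor in (0, 1]; 1 = unoccluded.
#' @param viscosity_Pa_s,density_g_mm3 Blood properties.
#' @return A list of class `surrogate_spec`.
#' @export
surrogate_spec <- function(branch_R = c(RC = 1e-3, LC = 1e-3, RS = 1e-3,
                                        LS = 1e-3, DAo = 1e-3),
                           pa_branch_R = c(LPA = 1e-3, RPA = 1e-3),
                           shunt_mode = c("empirical", "poiseuille"),
                           shunt_R = 3.5,
                           shunt_diameter_mm = 3.5, shunt_length_mm = 14,
                           scale = 1,
                           viscosity_Pa_s = 0.004,
                           density_g_mm3 = 0.00106) {
  shunt_mode <- match.arg(shunt_mode)
  if (any(branch_R < 0) || any(pa_branch_R < 0))
    stop("surrogate branch resistances must be non-negative", call. = FALSE)
  miss <- setdiff(SURROGATE_BRANCHES, names(branch_R))
  if (length(miss))
    stop("surrogate missing branch(es): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(c("LPA", "RPA") %in% names(pa_branch_R)))
    stop("surrogate requires LPA and RPA junction branches", call. = FALSE)
  if (shunt_diameter_mm <= 0 || shunt_length_mm <= 0)
    stop("shunt geometry must be positive", call. = FALSE)
  if (scale <= 0 || scale > 1)
    stop("diameter scale factor must lie in (0, 1]", call. = FALSE)
  if (shunt_mode == "empirical" && shunt_R <= 0)
    stop("empirical shunt resistance must be positive", call. = FALSE)
  structure(list(branch_R = branch_R, pa_branch_R = pa_branch_R,
                 shunt_mode = shunt_mode, shunt_R = shunt_R,
                 shunt_diameter_mm = shunt_diameter_mm,
                 shunt_length_mm = shunt_length_mm, scale = scale,
                 viscosity_Pa_s = viscosity_Pa_s,
                 density_g_mm3 = density_g_mm3),
            class = "surrogate_spec")
}

#' Hagen-Poiseuille resistance of a cylindrical tube
#'
#' `R = 128 * mu * L / (pi * d^4)`, converted to mmHg*s/ml
#' (1 mmHg = 133.322 Pa; 1 ml = 1000 mm^3).
#'
#' @param diameter_mm,length_mm Tube geometry (mm, > 0).
#' @param viscosity_Pa_s Dynamic viscosity (Pa*s, > 0).
#' @return Resistance in mmHg*s/ml.
#' @export
poiseuille_resistance <- function(diameter_mm, length_mm,
                                  viscosity_Pa_s = 0.004) {
  if (any(diameter_mm <= 0) || any(length_mm <= 0) || any(viscosity_Pa_s <= 0))
    stop("poiseuille_resistance requires strictly positive inputs",
         call. = FALSE)
  R_pa_s_mm3 <- 128 * viscosity_Pa_s * length_mm / (pi * diameter_mm^4)
  R_pa_s_mm3 * MMHG_PER_PA * 1000
}

#' Effective (lumped) resistance from mean gradient and mean flow
#'
#' The equivalent-resistance descriptor used to characterise shunt occlusion:
#' mean trans-shunt pressure gradient divided by mean shunt flow.
#'
#' @param mean_gradient_mmHg Mean pressure gradient (mmHg, >= 0).
#' @param mean_flow_mls Mean flow (ml/s, > 0).
#' @return Resistance in mmHg*s/ml.
#' @export
effective_resistance <- function(mean_gradient_mmHg, mean_flow_mls) {
  if (any(mean_flow_mls <= 0))
    stop("effective_resistance requires strictly positive flow", call. = FALSE)
  mean_gradient_mmHg / mean_flow_mls
}

#' Trans-shunt pressure gradient
#'
#' @param mean_aortic_mmHg,mean_pulmonary_mmHg Mean pressures (mmHg).
#' @return Aortic minus pulmonary pressure (mmHg).
#' @export
pressure_gradient <- function(mean_aortic_mmHg, mean_pulmonary_mmHg) {
  mean_aortic_mmHg - mean_pulmonary_mmHg
}

#' Reynolds number of tube flow
#'
#' `Re = rho * v * d / mu` with the cross-section mean velocity
#' `v = Q / (pi d^2 / 4)`. With flow in mm^3/s, diameter in mm, density in
#' g/mm^3 and viscosity in Pa*s (= g/(mm*s)) the result is dimensionless.
#'
#' @param flow_mm3_s Volumetric flow (mm^3/s, >= 0).
#' @param diameter_mm Tube diameter (mm, > 0).
#' @param density_g_mm3,viscosity_Pa_s Fluid properties (> 0).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(flow_mm3_s, diameter_mm,
                            density_g_mm3 = 0.00106, viscosity_Pa_s = 0.004) {
  if (any(diameter_mm <= 0) || any(density_g_mm3 <= 0) ||
      any(viscosity_Pa_s <= 0))
    stop("reynolds_number requires strictly positive diameter and fluid properties",
         call. = FALSE)
  if (any(flow_mm3_s < 0))
    stop("reynolds_number requires non-negative flow", call. = FALSE)
  v_mm_s <- flow_mm3_s / (pi * diameter_mm^2 / 4)
  density_g_mm3 * v_mm_s * diameter_mm / viscosity_Pa_s
}

#' Shunt resistance implied by a surrogate specification
#'
#' Empirical mode returns the configured effective resistance; Poiseuille mode
#' returns the tube resistance at the occluded diameter
#' (`scale * shunt_diameter_mm`).
#'
#' @param spec A [surrogate_spec()].
#' @return Resistance in mmHg*s/ml.
#' @export
surrogate_shunt_resistance <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  if (spec$shunt_mode == "empirical") spec$shunt_R
  else poiseuille_resistance(spec$scale * spec$shunt_diameter_mm,
                             spec$shunt_length_mm, spec$viscosity_Pa_s)
}

#' Build the surrogate resistor network
#'
#' Eight resistors: `aoroot` to each of the five great-vessel Windkessel entry
#' nodes, the shunt from `aoroot` to the pulmonary junction `pa_j`, and `pa_j`
#' to the `LPA`/`RPA` entry nodes.
#'
#' @param spec A [surrogate_spec()].
#' @return List of `lpn_component` resistors.
#' @export
build_surrogate_network <- function(spec = surrogate_spec()) {
  stopifnot(inherits(spec, "surrogate_spec"))
  comps <- lapply(SURROGATE_BRANCHES, function(b)
    lpn_component("resistor", paste0("sur_", b), "aoroot", paste0(b, "_in"),
                  R = max(spec$branch_R[[b]], .Machine$double.eps)))
  comps <- c(comps, list(
    lpn_component("resistor", "shunt", "aoroot", "pa_j",
                  R = surrogate_shunt_resistance(spec)),
    lpn_component("resistor", "sur_LPA", "pa_j", "LPA_in",
                  R = max(spec$pa_branch_R[["LPA"]], .Machine$double.eps)),
    lpn_component("resistor", "sur_RPA", "pa_j", "RPA_in",
                  R = max(spec$pa_branch_R[["RPA"]], .Machine$double.eps))
  ))
  comps
}
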