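# Inference of effective shunt occlusion from trans-shunt hemodynamics.
# The shunt is characterised by its equivalent lumped resistance; occlusion
# is expressed as a diameter scale factor via the Hagen-Poiseuille d^-4 law.

#' Diameter scale factor from a resistance ratio
#'
#' Applies the Poiseuille `d^-4` law to the resistance that must change:
#' `scale = (R_ref / R_target)^(1/4)`, the factor by which the diameter must
#' shrink for a tube of resistance `R_ref` to reach `R_target`.
#'
#' @param R_ref,R_target Reference and target resistances (mmHg*s/ml, > 0).
#' @return Dimensionless scale factor.
#' @export
scale_from_resistance_ratio <- function(R_ref, R_target) {
  if (any(R_ref <= 0) || any(R_target <= 0))
    stop("resistances must be strictly positive", call. = FALSE)
  (R_ref / R_target)^(1 / 4)
}

new_occlusion_estimate <- function(scale, method, R_ref = NA_real_,
                                   R_target = NA_real_, extra = list()) {
  est <- c(list(
    scale = scale,
    diameter_reduction_pct = 100 * (1 - scale),
    area_occlusion_pct = 100 * (1 - scale^2),
    reference_resistance = R_ref,
    target_resistance = R_target,
    method = method), extra)
  class(est) <- "occlusion_estimate"
  est
}

#' @export
print.occlusion_estimate <- function(x, ...) {
  cat("occlusion_estimate (method: ", x$method, ")\n", sep = "")
  cat("  diameter scale factor: ", signif(x$scale, 4), "\n", sep = "")
  cat("  diameter reduction:    ",
      round_half_away(x$diameter_reduction_pct), "%\n", sep = "")
  cat("  area occlusion:        ",
      round_half_away(x$area_occlusion_pct), "%\n", sep = "")
  if (is.finite(x$reference_resistance))
    cat("  resistance: ", signif(x$reference_resistance, 3), " -> ",
        signif(x$target_resistance, 3), " mmHg*s/ml\n", sep = "")
  if (!is.null(x$converged))
    cat("  converged: ", x$converged, " (", x$iterations, " simulations)\n",
        sep = "")
  invisible(x)
}

#' Occlusion metrics from nominal and effective diameters
#'
#' @param d_nominal_mm Manufactured (nominal) diameter (mm).
#' @param d_effective_mm Effective (occluded) diameter (mm),
#'   `0 < d_effective_mm <= d_nominal_mm`.
#' @return An `occlusion_estimate` with diameter reduction
#'   `100 * (1 - scale)` and area occlusion `100 * (1 - scale^2)` percent
#'   (printed rounded to the nearest integer).
#' @export
occlusion_metrics <- function(d_nominal_mm, d_effective_mm) {
  if (d_effective_mm <= 0 || d_nominal_mm <= 0)
    stop("diameters must be positive", call. = FALSE)
  if (d_effective_mm > d_nominal_mm)
    stop("effective diameter exceeds the nominal diameter", call. = FALSE)
  new_occlusion_estimate(d_effective_mm / d_nominal_mm, "poiseuille_scaling",
                         extra = list(d_nominal_mm = d_nominal_mm,
                                      d_effective_mm = d_effective_mm))
}

#' Closed-form occlusion estimate from resistances
#'
#' Convenience wrapper combining [scale_from_resistance_ratio()] and the
#' occlusion percentages.
#'
#' @param R_ref Resistance of the unoccluded reference tube (mmHg*s/ml).
#' @param R_target Resistance the occluded tube must present, either given
#'   directly or as `gradient / flow`.
#' @param gradient_mmHg,flow_mls Alternative specification of `R_target`.
#' @return An `occlusion_estimate` with method `"poiseuille_scaling"`.
#' @export
occlusion_from_resistances <- function(R_ref, R_target = NULL,
                                       gradient_mmHg = NULL, flow_mls = NULL) {
  if (is.null(R_target)) {
    if (is.null(gradient_mmHg) || is.null(flow_mls))
      stop("supply R_target or both gradient_mmHg and flow_mls", call. = FALSE)
    R_target <- effective_resistance(gradient_mmHg, flow_mls)
  }
  sc <- scale_from_resistance_ratio(R_ref, R_target)
  new_occlusion_estimate(min(sc, 1), "poiseuille_scaling", R_ref, R_target)
}

#' Infer shunt occlusion by iterative closed-loop simulation
#'
#' Treats the shunt resistance as a monotone function of the diameter scale
#' factor, `R(s) = R(1) / s^4`, and bisects on the scale until the simulated
#' mean trans-shunt pressure gradient and mean shunt flow are both within
#' `tol` (relative) of the supplied targets. Monotonicity of the gradient in
#' the scale is asserted at the bracket ends. Simulations are warm-started
#' from the previous periodic state.
#'
#' @param config A [patient_config()]; its surrogate defines `R(1)` (the
#'   shunt resistance at scale 1).
#' @param target_gradient_mmHg,target_flow_mls Measured mean trans-shunt
#'   gradient and mean shunt flow.
#' @param tol Relative tolerance on both targets (default 0.10).
#' @param bracket Scale bracket (default `c(0.3, 1)`).
#' @param max_iter Maximum number of simulations.
#' @return An `occlusion_estimate` with method `"iterative_simulation"`,
#'   fields `achieved_gradient_mmHg`, `achieved_flow_mls`, `iterations` and
#'   `converged`.
#' @export
infer_occlusion_by_simulation <- function(config, target_gradient_mmHg,
                                          target_flow_mls, tol = 0.10,
                                          bracket = c(0.3, 1),
                                          max_iter = 40) {
  stopifnot(inherits(config, "lpn_config"), target_gradient_mmHg > 0,
            target_flow_mls > 0, tol >= 0, bracket[1] > 0,
            bracket[1] < bracket[2], bracket[2] <= 1)
  R1 <- if (config$surrogate$shunt_mode == "empirical")
    config$surrogate$shunt_R else
    surrogate_shunt_resistance(within_scale(config$surrogate, 1))
  warm <- NULL
  evaluate <- function(s) {
    cfg <- config
    cfg$surrogate <- within_scale(cfg$surrogate, s, R1)
    res <- run_model(cfg, init = warm)
    warm <<- res$final_state
    ms <- shunt_means(res)
    list(gradient = ms$gradient, flow = ms$flow)
  }
  lo <- bracket[1]; hi <- bracket[2]
  e_lo <- evaluate(lo); e_hi <- evaluate(hi)
  iters <- 2L
  if (!(e_lo$gradient > e_hi$gradient))
    stop("trans-shunt gradient is not monotone decreasing in the diameter scale ",
         "over the bracket; cannot bisect", call. = FALSE)
  ok <- function(e) {
    tol > 0 &&
      abs(e$gradient - target_gradient_mmHg) <= tol * target_gradient_mmHg &&
      abs(e$flow - target_flow_mls) <= tol * target_flow_mls
  }
  finish <- function(s, e, converged) {
    new_occlusion_estimate(s, "iterative_simulation", R1, R1 / s^4,
      extra = list(achieved_gradient_mmHg = e$gradient,
                   achieved_flow_mls = e$flow,
                   iterations = iters, converged = converged))
  }
  if (ok(e_lo)) return(finish(lo, e_lo, TRUE))
  if (ok(e_hi)) return(finish(hi, e_hi, TRUE))
  if (target_gradient_mmHg > e_lo$gradient || target_gradient_mmHg < e_hi$gradient)
    return(finish(if (target_gradient_mmHg > e_lo$gradient) lo else hi,
                  if (target_gradient_mmHg > e_lo$gradient) e_lo else e_hi,
                  FALSE))
  mid <- NA_real_; e_mid <- NULL
  while (iters < max_iter && (hi - lo) > 1e-5) {
    mid <- (lo + hi) / 2
    e_mid <- evaluate(mid)
    iters <- iters + 1L
    if (ok(e_mid)) return(finish(mid, e_mid, TRUE))
    if (e_mid$gradient > target_gradient_mmHg) lo <- mid else hi <- mid
  }
  finish(if (is.na(mid)) lo else mid,
         if (is.null(e_mid)) e_lo else e_mid, FALSE)
}

# Rescale a surrogate spec to a diameter scale factor s. In empirical mode
# the shunt resistance follows the d^-4 law relative to R(1) = R1.
within_scale <- function(surrogate, s, R1 = NULL) {
  if (surrogate$shunt_mode == "empirical") {
    if (is.null(R1)) R1 <- surrogate$shunt_R
    surrogate$shunt_R <- R1 / s^4
    surrogate$scale <- s
  } else {
    surrogate$scale <- s
  }
  surrogate
}

# Cycle-mean trans-shunt gradient (aortic root minus PA junction) and mean
# shunt flow of a simulated result.
shunt_means <- function(result) {
  sel <- seq(2L, nrow(result$P))
  gradient <- mean(result$P[sel, "aoroot"] - result$P[sel, "pa_j"])
  flow <- mean(component_flow(result, "shunt")[sel])
  list(gradient = gradient, flow = flow)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
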