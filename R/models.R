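# Run configurations and builtin patient models.

BUILTIN_SHUNT_R <- c(baseline = 3.5, flared = 3.3, implant_time = 2.1)

#' Simulation run configuration
#'
#' Bundles the circuit specification (parameter tables, surrogate, heart)
#' with solver settings. The builtin model names select the empirical shunt
#' resistance: `"baseline"` 3.5, `"flared"` 3.3 and `"implant_time"`
#' 2.1 mmHg*s/ml.
#'
#' @param model Builtin model name, or `NULL` when a custom `surrogate` is
#'   supplied.
#' @param dt Time step (s, > 0).
#' @param period Cycle length (s).
#' @param max_cycles,tol Periodic-convergence controls (`tol` > 0).
#' @param P0 Uniform initial pressure (mmHg).
#' @param seed Optional integer seed recorded with the config.
#' @param tables,surrogate,heart Circuit specification; defaults are the
#'   packaged tables, the builtin-model surrogate and [heart_spec()].
#' @param collateral1_nodes,collateral2_nodes Collateral attachment nodes,
#'   passed to [build_patient_circuit()].
#' @return A list of class `lpn_config`.
#' @export
patient_config <- function(model = c("baseline", "flared", "implant_time"),
                           dt = 1e-4, period = 0.46, max_cycles = 60,
                           tol = 1e-3, P0 = 10, seed = NULL,
                           tables = default_parameter_tables(),
                           surrogate = NULL, heart = NULL,
                           collateral1_nodes = NULL,
                           collateral2_nodes = NULL) {
  if (is.null(surrogate)) {
    model <- match.arg(model)
    surrogate <- surrogate_spec(shunt_R = BUILTIN_SHUNT_R[[model]])
  } else model <- if (is.character(model) && length(model) == 1L &&
                      model %in% names(BUILTIN_SHUNT_R)) model else "custom"
  if (is.null(heart)) heart <- heart_spec(period = period)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(model = model, dt = dt, period = period,
                 max_cycles = max_cycles, tol = tol, P0 = P0, seed = seed,
                 tables = tables, surrogate = surrogate, heart = heart,
                 collateral1_nodes = collateral1_nodes,
                 collateral2_nodes = collateral2_nodes),
            class = "lpn_config")
}

#' Build the netlist described by a configuration
#'
#' @param config An `lpn_config`.
#' @return A validated `lpn_netlist`.
#' @export
config_netlist <- function(config) {
  stopifnot(inherits(config, "lpn_config"))
  args <- list(tables = config$tables, surrogate = config$surrogate,
               heart = config$heart)
  if (!is.null(config$collateral1_nodes))
    args$collateral1_nodes <- config$collateral1_nodes
  if (!is.null(config$collateral2_nodes))
    args$collateral2_nodes <- config$collateral2_nodes
  do.call(build_patient_circuit, args)
}

#' Run a configured model to periodic steady state
#'
#' @param config An `lpn_config`.
#' @param init Optional warm-start state (see [run_to_periodic()]).
#' @return An `lpn_result`.
#' @export
run_model <- function(config, init = NULL) {
  stopifnot(inherits(config, "lpn_config"))
  run_to_periodic(config_netlist(config), period = config$period,
                  dt = config$dt, max_cycles = config$max_cycles,
                  tol = config$tol, init = init, P0 = config$P0)
}
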