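# File formats: text netlists, waveform CSVs, configuration and target JSON.
# All numeric round-trips are lossless (17 significant digits).

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a netlist to its text format
#'
#' One component per line: `KIND name node_from node_to key=value ...`;
#' `#` starts a comment; identifiers are case-sensitive. The reference node
#' is written as a `REF <node>` line. Elastance chambers are representable
#' when their elastance is parametric (Gaussian parameter list); tabulated
#' or functional elastances cannot be serialized to this format.
#'
#' @param netlist An `lpn_netlist`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_netlist <- function(netlist, path) {
  stopifnot(inherits(netlist, "lpn_netlist"))
  lines <- c("# btlpn netlist (mmHg, ml/s, ml, s)", paste("REF", netlist$ref))
  for (cp in netlist$components) {
    p <- cp$parameters
    if (cp$kind == "elastance_chamber") {
      E <- p$E
      if (!(is.list(E) && !inherits(E, "elastance_curve") &&
            all(c("E_min", "E_max", "t0", "sigma", "period") %in% names(E))))
        stop("elastance_chamber '", cp$name, "' has a non-parametric ",
             "elastance and cannot be written to the text netlist format",
             call. = FALSE)
      p <- c(E[c("E_min", "E_max", "t0", "sigma", "period")],
             p[c("V0", "V_init")])
    }
    if (any(vapply(p, is.function, TRUE)))
      stop("component '", cp$name, "' has a functional parameter and cannot ",
           "be written to the text netlist format", call. = FALSE)
    kv <- paste0(names(p), "=", vapply(p, fmt_num, ""))
    lines <- c(lines, paste(cp$kind, cp$name, cp$node_from, cp$node_to,
                            paste(kv, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a netlist from its text format
#'
#' @param path Input file (see [write_netlist()] for the format).
#' @return A validated `lpn_netlist`.
#' @export
read_netlist <- function(path) {
  lines <- readLines(path)
  ref <- "ground"
  comps <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (tok[1L] == "REF") {
      if (length(tok) != 2L)
        stop("line ", i, ": REF takes exactly one node identifier",
             call. = FALSE)
      ref <- tok[2L]
      next
    }
    if (length(tok) < 4L)
      stop("line ", i, ": expected 'KIND name node_from node_to key=value ...'",
           call. = FALSE)
    if (!tok[1L] %in% COMPONENT_KINDS)
      stop("line ", i, ": unknown component kind '", tok[1L],
           "'; valid kinds: ", paste(COMPONENT_KINDS, collapse = ", "),
           call. = FALSE)
    params <- list()
    for (kv in tok[-(1:4)]) {
      m <- regmatches(kv, regexec("^([^=]+)=(.+)$", kv))[[1L]]
      if (length(m) != 3L)
        stop("line ", i, ": malformed parameter '", kv, "'", call. = FALSE)
      v <- suppressWarnings(as.numeric(m[3L]))
      if (is.na(v))
        stop("line ", i, ": non-numeric value in '", kv, "'", call. = FALSE)
      params[[m[2L]]] <- v
    }
    if (tok[1L] == "elastance_chamber") {
      ek <- c("E_min", "E_max", "t0", "sigma", "period")
      if (!all(ek %in% names(params)))
        stop("line ", i, ": elastance_chamber requires keys ",
             paste(ek, collapse = ", "), call. = FALSE)
      params <- c(list(E = params[ek]),
                  params[setdiff(names(params), ek)])
    }
    comps[[length(comps) + 1L]] <-
      do.call(lpn_component, c(list(tok[1L], tok[2L], tok[3L], tok[4L]),
                               params))
  }
  lpn_netlist(comps, ref = ref)
}

#' Write simulated waveforms to CSV
#'
#' Columns: `time_s`, one `P_<node>_mmHg` per node pressure, one
#' `Q_<name>_mls` per tracked branch flow (plus any components named in
#' `flows`, recomputed via [component_flow()]).
#'
#' @param result An `lpn_result`.
#' @param path Output file.
#' @param flows Extra component names whose flows to include.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(result, path, flows = character()) {
  df <- data.frame(time_s = result$time)
  for (nd in colnames(result$P))
    df[[paste0("P_", nd, "_mmHg")]] <- result$P[, nd]
  for (bn in colnames(result$Q))
    df[[paste0("Q_", bn, "_mls")]] <- result$Q[, bn]
  for (fn in flows)
    df[[paste0("Q_", fn, "_mls")]] <- component_flow(result, fn)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a waveform / time-series CSV
#'
#' Requires a `time_s` column with strictly increasing values.
#'
#' @param path Input file.
#' @return A data.frame.
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df))
    stop("waveform CSV must contain a 'time_s' column", call. = FALSE)
  if (any(diff(df$time_s) <= 0))
    stop("waveform CSV has non-monotone time values", call. = FALSE)
  df
}

config_defaults <- function() {
  list(model = "baseline", dt = 1e-4, period = 0.46, max_cycles = 60,
       tol = 1e-3, P0 = 10, seed = NULL)
}

#' Write a run configuration to JSON
#'
#' One flat JSON document mirroring the parameter tables (outlet and venous
#' section names as keys), the surrogate block and the heart block. Only
#' parametric (Gaussian) elastances are representable.
#'
#' @param config An `lpn_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "lpn_config"))
  h <- config$heart
  if (!(is.list(h$elastance) && !inherits(h$elastance, "elastance_curve") &&
        !is.function(h$elastance)))
    stop("only parametric (Gaussian) elastances can be written to config JSON",
         call. = FALSE)
  doc <- list(
    model = config$model, dt = config$dt, period = config$period,
    max_cycles = config$max_cycles, tol = config$tol, P0 = config$P0,
    seed = config$seed,
    tables = list(
      windkessel_outlets = lapply(config$tables$windkessel_outlets,
                                  function(w) w[c("Rp", "Rd", "C")]),
      venous_sections = lapply(config$tables$venous_sections,
                               function(w) w[c("Rp", "Rd", "C")]),
      heart_and_shunts = as.list(config$tables$heart_and_shunts)
    ),
    surrogate = {
      s <- unclass(config$surrogate)
      s$branch_R <- as.list(s$branch_R)
      s$pa_branch_R <- as.list(s$pa_branch_R)
      s
    },
    heart = list(elastance = h$elastance, V0 = h$V0, EDV = h$EDV,
                 C_RA = h$C_RA, C_LA = h$C_LA, period = h$period),
    collateral1_nodes = config$collateral1_nodes,
    collateral2_nodes = config$collateral2_nodes
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' Missing solver keys fall back to package defaults; each applied default
#' is reported via `message()`.
#'
#' @param path Input file.
#' @return An `lpn_config`.
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c(names(config_defaults()), "tables", "surrogate", "heart",
             "collateral1_nodes", "collateral2_nodes")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(known, collapse = ", "), call. = FALSE)
  defs <- config_defaults()
  for (k in names(defs)) {
    if (is.null(doc[[k]]) && !is.null(defs[[k]])) {
      doc[[k]] <- defs[[k]]
      message("config: '", k, "' missing, default ", defs[[k]], " applied")
    }
  }
  tables <- if (is.null(doc$tables)) default_parameter_tables() else {
    wkify <- function(lst) lapply(lst, function(w)
      windkessel_params(w$Rp, w$Rd, w$C))
    structure(list(
      windkessel_outlets = wkify(doc$tables$windkessel_outlets),
      venous_sections = wkify(doc$tables$venous_sections),
      heart_and_shunts = unlist(doc$tables$heart_and_shunts)
    ), class = "parameter_tables")
  }
  surrogate <- if (is.null(doc$surrogate)) NULL else {
    s <- doc$surrogate
    surrogate_spec(branch_R = unlist(s$branch_R),
                   pa_branch_R = unlist(s$pa_branch_R),
                   shunt_mode = s$shunt_mode, shunt_R = s$shunt_R,
                   shunt_diameter_mm = s$shunt_diameter_mm,
                   shunt_length_mm = s$shunt_length_mm, scale = s$scale,
                   viscosity_Pa_s = s$viscosity_Pa_s,
                   density_g_mm3 = s$density_g_mm3)
  }
  heart <- if (is.null(doc$heart)) NULL else
    heart_spec(elastance = as.list(doc$heart$elastance), V0 = doc$heart$V0,
               EDV = doc$heart$EDV, C_RA = doc$heart$C_RA,
               C_LA = doc$heart$C_LA, period = doc$heart$period)
  patient_config(model = doc$model, dt = doc$dt, period = doc$period,
                 max_cycles = doc$max_cycles, tol = doc$tol, P0 = doc$P0,
                 seed = doc$seed, tables = tables, surrogate = surrogate,
                 heart = heart,
                 collateral1_nodes = doc$collateral1_nodes,
                 collateral2_nodes = doc$collateral2_nodes)
}

#' Write / read clinical targets JSON
#'
#' Per-index records with `value`, `rule` (`rel` | `range` | `none`), `tol`
#' and range `lower`/`upper`.
#'
#' @param targets A `clinical_targets` data.frame.
#' @param path File path.
#' @return `write_targets` returns `path` invisibly; `read_targets` a
#'   `clinical_targets` table.
#' @export
write_targets <- function(targets, path) {
  jsonlite::write_json(as.data.frame(targets), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("index", "value", "rule", "tol", "lower", "upper")
  miss <- setdiff(need, names(df))
  for (k in miss) df[[k]] <- NA_real_
  clinical_targets(df$index, as.numeric(df$value), df$rule,
                   as.numeric(df$tol), as.numeric(df$lower),
                   as.numeric(df$upper))
}

#' Write / read a hemodynamic summary JSON
#'
#' @param summary A `hemodynamic_summary`.
#' @param path File path.
#' @return `write_summary` returns `path` invisibly; `read_summary` a
#'   `hemodynamic_summary`.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(as.data.frame(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("index", "value") %in% names(df)))
    stop("summary JSON must contain 'index' and 'value'", call. = FALSE)
  structure(data.frame(index = df$index, value = as.numeric(df$value)),
            class = c("hemodynamic_summary", "data.frame"))
}
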