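# Circuit data model for closed-loop lumped-parameter circulations.
# Unit convention throughout the package: pressure mmHg, flow ml/s, volume ml,
# time s, resistance mmHg*s/ml, compliance ml/mmHg, inertance mmHg*s^2/ml.

COMPONENT_KINDS <- c("resistor", "capacitor", "inductor", "diode_valve",
                     "elastance_chamber", "flow_source", "pressure_source")

#' Create a circuit component
#'
#' A component is a two-terminal circuit element between two named pressure
#' nodes. Flow is positive in the `node_from` to `node_to` direction; diode
#' valves conduct only in that direction.
#'
#' @param kind One of `"resistor"`, `"capacitor"`, `"inductor"`,
#'   `"diode_valve"`, `"elastance_chamber"`, `"flow_source"`,
#'   `"pressure_source"`.
#' @param name Unique component identifier.
#' @param node_from,node_to Node identifiers (non-empty, distinct).
#' @param ... Named parameters. Required by kind:
#'   resistor `R`; capacitor `C` (optional `V0`, the volume stored at zero
#'   transmural pressure, used only for volume bookkeeping); inductor `L`;
#'   diode_valve `R` and `L` (open-state resistance and inertance);
#'   elastance_chamber `E` (a function of time in s returning mmHg/ml, an
#'   [elastance_curve], or a named list of Gaussian parameters
#'   `E_min, E_max, t0, sigma, period`), `V0` (unstressed volume ml) and
#'   `V_init` (initial volume ml); flow_source `Q` (scalar ml/s or function of
#'   time); pressure_source `P` (scalar mmHg or function of time).
#' @return An object of class `lpn_component`.
#' @export
lpn_component <- function(kind, name, node_from, node_to, ...) {
  kind <- match.arg(kind, COMPONENT_KINDS)
  params <- list(...)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("component name must be a non-empty string", call. = FALSE)
  for (nd in c(node_from, node_to))
    if (!is.character(nd) || length(nd) != 1L || !nzchar(nd))
      stop("node identifiers must be non-empty strings (component '", name, "')",
           call. = FALSE)
  if (identical(node_from, node_to))
    stop("node_from and node_to must differ (component '", name, "')",
         call. = FALSE)

  need_pos <- function(key) {
    v <- params[[key]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("component '", name, "' (", kind, ") requires strictly positive '",
           key, "'", call. = FALSE)
    v
  }
  switch(kind,
    resistor = need_pos("R"),
    capacitor = {
      need_pos("C")
      if (is.null(params$V0)) params$V0 <- 0
    },
    inductor = need_pos("L"),
    diode_valve = { need_pos("R"); need_pos("L") },
    elastance_chamber = {
      if (is.null(params$E))
        stop("elastance_chamber '", name, "' requires an elastance 'E'",
             call. = FALSE)
      if (is.null(params$V0)) params$V0 <- 0
      if (is.null(params$V_init))
        stop("elastance_chamber '", name, "' requires 'V_init'", call. = FALSE)
    },
    flow_source = {
      if (is.null(params$Q)) stop("flow_source '", name, "' requires 'Q'",
                                  call. = FALSE)
    },
    pressure_source = {
      if (is.null(params$P)) stop("pressure_source '", name, "' requires 'P'",
                                  call. = FALSE)
    }
  )
  structure(list(kind = kind, name = name, node_from = node_from,
                 node_to = node_to, parameters = params),
            class = "lpn_component")
}

#' Three-element Windkessel parameter set
#'
#' Proximal resistance `Rp`, distal resistance `Rd` (mmHg*s/ml), compliance
#' `C` (ml/mmHg) and distal pressure `Pd` (mmHg). `Pd` is a fixed value only
#' in stand-alone use; in a closed-loop assembly the distal terminal is a
#' solved circuit node.
#'
#' @param Rp,Rd,C Strictly positive scalars.
#' @param Pd Distal pressure (mmHg), used when the subcircuit is closed with a
#'   pressure source.
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(Rp, Rd, C, Pd = 0) {
  for (v in list(Rp = Rp, Rd = Rd, C = C)) stopifnot(is.numeric(v), length(v) == 1L)
  if (Rp <= 0 || Rd <= 0 || C <= 0)
    stop("Windkessel Rp, Rd and C must be strictly positive", call. = FALSE)
  structure(list(Rp = Rp, Rd = Rd, C = C, Pd = Pd), class = "windkessel_params")
}

#' Build a three-element Windkessel subcircuit
#'
#' Returns the component list of an Rp-series plus parallel Rd/C outlet model:
#' `node_in --Rp--> mid --Rd--> distal`, with the compliance from `mid` to the
#' reference node. With `closed_loop = FALSE` a pressure source pins the
#' distal node to `params$Pd`; with `closed_loop = TRUE` the distal node is
#' left open for connection to a downstream (venous) network.
#'
#' @param name Prefix for component and node names.
#' @param params A [windkessel_params].
#' @param closed_loop Leave the distal node open (`TRUE`) or pin it (`FALSE`).
#' @param node_in,node_out Optional node identifiers for the entry and distal
#'   terminals; defaults are `<name>_in` and `<name>_out`.
#' @param ref Reference node identifier.
#' @return List of `lpn_component`.
#' @export
make_windkessel <- function(name, params, closed_loop = FALSE,
                            node_in = paste0(name, "_in"),
                            node_out = paste0(name, "_out"),
                            ref = "ground") {
  stopifnot(inherits(params, "windkessel_params"))
  mid <- paste0(name, "_mid")
  comps <- list(
    lpn_component("resistor", paste0(name, "_Rp"), node_in, mid, R = params$Rp),
    lpn_component("capacitor", paste0(name, "_C"), mid, ref, C = params$C),
    lpn_component("resistor", paste0(name, "_Rd"), mid, node_out, R = params$Rd)
  )
  if (!closed_loop)
    comps <- c(comps, list(lpn_component("pressure_source", paste0(name, "_Pd"),
                                         node_out, ref, P = params$Pd)))
  comps
}

#' Assemble a netlist
#'
#' @param components List of [lpn_component] (or of lists of them, which are
#'   flattened).
#' @param ref Reference (zero-pressure) node identifier.
#' @param validate Run [validate_netlist] on the result.
#' @return An object of class `lpn_netlist` with fields `components`, `nodes`
#'   and `ref`.
#' @export
lpn_netlist <- function(components, ref = "ground", validate = TRUE) {
  flat <- list()
  for (x in components) {
    if (inherits(x, "lpn_component")) flat[[length(flat) + 1L]] <- x
    else if (is.list(x)) for (y in x) {
      stopifnot(inherits(y, "lpn_component"))
      flat[[length(flat) + 1L]] <- y
    } else stop("components must be lpn_component objects", call. = FALSE)
  }
  nodes <- unique(c(vapply(flat, `[[`, "", "node_from"),
                    vapply(flat, `[[`, "", "node_to")))
  nl <- structure(list(components = flat, nodes = nodes, ref = ref),
                  class = "lpn_netlist")
  if (validate) validate_netlist(nl)
  nl
}

#' @export
print.lpn_netlist <- function(x, ...) {
  cat("lpn_netlist:", length(x$components), "components,",
      length(x$nodes), "nodes (reference:", x$ref, ")\n")
  tab <- table(vapply(x$components, `[[`, "", "kind"))
  for (k in names(tab)) cat("  ", k, ": ", tab[[k]], "\n", sep = "")
  invisible(x)
}

#' Validate a netlist
#'
#' Checks component-name uniqueness, presence and uniqueness of the reference
#' node, graph connectivity (every node reachable from the reference through
#' components), and positivity of element parameters. Raises an error naming
#' the offending node or component on violation.
#'
#' @param n An `lpn_netlist`.
#' @return Invisibly, a list of diagnostics (`n_components`, `n_nodes`,
#'   `connected`, `kinds`).
#' @export
validate_netlist <- function(n) {
  stopifnot(inherits(n, "lpn_netlist"))
  nms <- vapply(n$components, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate component name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  if (!(n$ref %in% n$nodes))
    stop("reference node '", n$ref, "' does not appear in any component",
         call. = FALSE)
  # connectivity by breadth-first search from the reference node
  adj <- list()
  for (cp in n$components) {
    adj[[cp$node_from]] <- c(adj[[cp$node_from]], cp$node_to)
    adj[[cp$node_to]] <- c(adj[[cp$node_to]], cp$node_from)
  }
  seen <- n$ref
  frontier <- n$ref
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  isolated <- setdiff(n$nodes, seen)
  if (length(isolated))
    stop("node(s) not connected to the reference node: ",
         paste(isolated, collapse = ", "), call. = FALSE)
  # element constructors already enforce positivity; re-check defensively for
  # netlists built by hand or read from disk
  for (cp in n$components) {
    p <- cp$parameters
    for (key in intersect(c("R", "C", "L"), names(p)))
      if (is.numeric(p[[key]]) && p[[key]] <= 0)
        stop("component '", cp$name, "' has non-positive ", key, call. = FALSE)
  }
  invisible(list(n_components = length(n$components),
                 n_nodes = length(n$nodes), connected = TRUE,
                 kinds = table(vapply(n$components, `[[`, "", "kind"))))
}
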