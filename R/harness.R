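# Clinical comparison harness: cycle-mean summaries at the model's
# comparison sites, percent-error scoring against clinical targets (10%
# relative rule, pulmonary-pressure range rule), and shunt-design
# percent-change tables.

#' Default site map: the 16 clinical comparison indices
#'
#' Six pressure indices (aortic root mean / systolic / diastolic / pulse,
#' LPA and RPA mean) and ten mean-flow indices (aortic root, descending
#' aorta, SVC, IVC, LPA, RPA, LPV, RPV, atrial septal defect, shunt), as
#' measured on the patient circuit built by [build_patient_circuit()].
#'
#' @return A data.frame with columns `index`, `type` (`pressure`/`flow`),
#'   `where` (node or component name) and `stat`.
#' @export
default_site_map <- function() {
  p <- function(index, node, stat) data.frame(index = index, type = "pressure",
                                              where = node, stat = stat)
  f <- function(index, comp) data.frame(index = index, type = "flow",
                                        where = comp, stat = "mean")
  rbind(
    p("aoroot_pressure_mean", "aoroot", "mean"),
    p("aoroot_pressure_systolic", "aoroot", "max"),
    p("aoroot_pressure_diastolic", "aoroot", "min"),
    p("aoroot_pressure_pulse", "aoroot", "pulse"),
    p("LPA_pressure_mean", "LPA_in", "mean"),
    p("RPA_pressure_mean", "RPA_in", "mean"),
    f("aoroot_flow_mean", "NAV"),
    f("DAo_flow_mean", "sur_DAo"),
    f("SVC_flow_mean", "SVC_Rp"),
    f("IVC_flow_mean", "IVC_Rp"),
    f("LPA_flow_mean", "sur_LPA"),
    f("RPA_flow_mean", "sur_RPA"),
    f("LPV_flow_mean", "LPV_Rp"),
    f("RPV_flow_mean", "RPV_Rp"),
    f("ASD_flow_mean", "ASD"),
    f("shunt_flow_mean", "shunt")
  )
}

#' Summarize a simulation at the clinical comparison sites
#'
#' Computes cycle statistics (mean, max, min, pulse = max - min) over the
#' final stored cycle for each mapped index.
#'
#' @param result A converged `lpn_result`.
#' @param site_map A data.frame as returned by [default_site_map()].
#' @return A `hemodynamic_summary`: data.frame with columns `index`, `value`
#'   (mmHg for pressures, ml/s for flows).
#' @export
summarize_hemodynamics <- function(result, site_map = default_site_map()) {
  sel <- seq(2L, nrow(result$P))
  val <- numeric(nrow(site_map))
  for (i in seq_len(nrow(site_map))) {
    row <- site_map[i, ]
    series <- if (row$type == "pressure") {
      if (!row$where %in% colnames(result$P))
        stop("unmapped pressure node '", row$where, "'", call. = FALSE)
      result$P[sel, row$where]
    } else {
      component_flow(result, row$where)[sel]
    }
    val[i] <- switch(row$stat,
                     mean = mean(series), max = max(series),
                     min = min(series), pulse = max(series) - min(series),
                     stop("unknown stat '", row$stat, "'", call. = FALSE))
  }
  structure(data.frame(index = site_map$index, value = val),
            class = c("hemodynamic_summary", "data.frame"))
}

#' Clinical target table
#'
#' @param index Character index names (matching the site map).
#' @param value Target values (NA for placeholder indices that are not
#'   scored).
#' @param rule Per-index rule: `"rel"` (percent error within `tol`),
#'   `"range"` (inclusive bounds), or `"none"` (placeholder, not scored).
#' @param tol Relative tolerance in percent (default 10).
#' @param lower,upper Bounds for `"range"` rows.
#' @return A `clinical_targets` data.frame.
#' @export
clinical_targets <- function(index, value, rule = "rel", tol = 10,
                             lower = NA_real_, upper = NA_real_) {
  df <- data.frame(index = index, value = value, rule = rule, tol = tol,
                   lower = lower, upper = upper)
  bad <- df$rule == "range" & !(df$lower < df$upper)
  if (any(bad, na.rm = TRUE))
    stop("range rule requires lower < upper (index ",
         paste(df$index[bad], collapse = ", "), ")", call. = FALSE)
  structure(df, class = c("clinical_targets", "data.frame"))
}

#' Packaged clinical targets of the reference case
#'
#' Encodes the recorded patient values that are stated numerically for the
#' reference case: mean aortic root pressure 56.4 mmHg and mean shunt flow
#' 9.7 ml/s (10% relative rule), and mean LPA/RPA pressures accepted
#' anywhere within the clinically reported 12.9-16.5 mmHg inter-artery
#' range. The remaining comparison indices were reported only graphically
#' and are included as unscored placeholders.
#'
#' @return A `clinical_targets` data.frame covering the 16 default indices.
#' @export
default_clinical_targets <- function() {
  idx <- default_site_map()$index
  tg <- clinical_targets(idx, value = NA_real_, rule = "none")
  set <- function(tg, index, value, rule, lower = NA_real_, upper = NA_real_) {
    i <- match(index, tg$index)
    tg$value[i] <- value; tg$rule[i] <- rule
    tg$lower[i] <- lower; tg$upper[i] <- upper
    tg
  }
  tg <- set(tg, "aoroot_pressure_mean", 56.4, "rel")
  tg <- set(tg, "shunt_flow_mean", 9.7, "rel")
  tg <- set(tg, "LPA_pressure_mean", 16.5, "range", 12.9, 16.5)
  tg <- set(tg, "RPA_pressure_mean", 12.9, "range", 12.9, 16.5)
  tg
}

#' Score a summary against clinical targets
#'
#' Percent error is `100 * |sim - target| / |target|` (the measured value in
#' the denominator). A `"rel"` index passes when the error is within its
#' tolerance; a `"range"` index passes when the simulated value lies within
#' the inclusive bounds; `"none"` rows are not scored.
#'
#' @param summary A `hemodynamic_summary`.
#' @param targets A `clinical_targets` table; every scored target index must
#'   be present in the summary.
#' @return A data.frame with per-index `simulated`, `target`,
#'   `percent_error`, `pass`; attributes `n_pass` and `n_scored`.
#' @export
score_against_targets <- function(summary, targets) {
  stopifnot(inherits(summary, "data.frame"), inherits(targets, "data.frame"))
  scored <- targets[targets$rule != "none", , drop = FALSE]
  miss <- setdiff(scored$index, summary$index)
  if (length(miss))
    stop("summary is missing target index(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sim <- summary$value[match(scored$index, summary$index)]
  perr <- rep(NA_real_, nrow(scored))
  pass <- logical(nrow(scored))
  for (i in seq_len(nrow(scored))) {
    tv <- scored$value[i]
    if (scored$rule[i] == "rel") {
      if (!is.finite(tv) || tv == 0)
        stop("relative rule undefined for zero/absent target '",
             scored$index[i], "'; use the range rule", call. = FALSE)
      perr[i] <- 100 * abs(sim[i] - tv) / abs(tv)
      pass[i] <- perr[i] <= scored$tol[i]
    } else { # range
      if (is.finite(tv) && tv != 0)
        perr[i] <- 100 * abs(sim[i] - tv) / abs(tv)
      pass[i] <- sim[i] >= scored$lower[i] && sim[i] <= scored$upper[i]
    }
  }
  out <- data.frame(index = scored$index, simulated = sim,
                    target = scored$value, rule = scored$rule,
                    percent_error = perr, pass = pass)
  attr(out, "n_pass") <- sum(pass)
  attr(out, "n_scored") <- nrow(out)
  out
}

#' Percent-change table between two designs
#'
#' `change % = 100 * (b - a) / a` per shared index; reported percentages are
#' rounded to the nearest integer, half away from zero; raw values are
#' retained. A zero baseline yields an undefined-change flag.
#'
#' @param a,b `hemodynamic_summary` objects (or data.frames with `index`,
#'   `value`) over the same index set.
#' @return Data.frame with `index`, `baseline`, `alternative`, `change_pct`,
#'   `change_pct_rounded`, `flag`.
#' @export
compare_designs <- function(a, b) {
  if (!setequal(a$index, b$index))
    stop("designs must be summarized over the same index set", call. = FALSE)
  bb <- b$value[match(a$index, b$index)]
  raw <- 100 * (bb - a$value) / a$value
  flag <- ifelse(a$value == 0, "undefined_baseline", "")
  raw[a$value == 0] <- NA_real_
  data.frame(index = a$index, baseline = a$value, alternative = bb,
             change_pct = raw,
             change_pct_rounded = round_half_away(raw),
             flag = flag)
}

#' Flag disagreements with published integer percent changes
#'
#' Compares the rounded percent changes of a [compare_designs()] table with
#' an externally published set of integer percentages and flags any
#' disagreement (typically a rounding artifact in the published table);
#' inputs are never adjusted to force agreement.
#'
#' @param change_table Output of [compare_designs()].
#' @param published Named integer vector (names = indices).
#' @return The change table with `published` and `match` columns for the
#'   compared rows.
#' @export
flag_change_mismatches <- function(change_table, published) {
  sel <- match(names(published), change_table$index)
  if (anyNA(sel))
    stop("published indices absent from the change table: ",
         paste(names(published)[is.na(sel)], collapse = ", "), call. = FALSE)
  out <- change_table[sel, , drop = FALSE]
  out$published <- as.numeric(published)
  out$match <- out$change_pct_rounded == out$published
  out$flag <- ifelse(out$match, out$flag, "published_rounding_mismatch")
  out
}
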