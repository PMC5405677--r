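# Patient-specific time-varying ventricular elastance construction.
#
# The elastance E(t) (mmHg/ml) is the time-varying ratio of ventricular
# pressure to volume above the unstressed volume. The systolic segment is
# measured directly (outflow-valve flow integrated from end-diastolic volume,
# pressure point-wise divided by volume); the remainder of the cycle is
# Gaussian-extrapolated, Fourier-smoothed to C1 continuity, and rescaled so
# the peak elastance is unchanged by smoothing.

#' Periodic elastance curve
#'
#' @param time Uniform sample times on `[0, period)` (s).
#' @param E Elastance samples (mmHg/ml, > 0).
#' @param period Cycle length (s).
#' @param segment Character vector per sample: `"measured"` (systolic,
#'   data-derived) or `"extrapolated"`.
#' @param V0 Unstressed volume used in the construction (ml).
#' @return An object of class `elastance_curve`.
#' @export
elastance_curve <- function(time, E, period, segment = rep("extrapolated",
                                                           length(E)),
                            V0 = 0) {
  stopifnot(length(time) == length(E), length(segment) == length(E),
            period > 0)
  if (any(E <= 0)) stop("elastance must be strictly positive", call. = FALSE)
  if (length(time) > 1) {
    dt <- diff(time)
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
      stop("elastance_curve requires a uniform time grid", call. = FALSE)
  }
  structure(list(time = time, E = E, period = period, segment = segment,
                 V0 = V0, peak = max(E)),
            class = "elastance_curve")
}

#' @export
print.elastance_curve <- function(x, ...) {
  cat("elastance_curve: period", x$period, "s,", length(x$E), "samples, peak",
      signif(x$peak, 4), "mmHg/ml (", sum(x$segment == "measured"),
      "measured samples )\n")
  invisible(x)
}

#' Periodic interpolating function of an elastance curve
#'
#' @param curve An `elastance_curve`.
#' @return A function of time (s) returning mmHg/ml, linearly interpolated
#'   and periodic.
#' @export
elastance_function <- function(curve) {
  stopifnot(inherits(curve, "elastance_curve"))
  tt <- c(curve$time, curve$period)
  ee <- c(curve$E, curve$E[1L])
  f <- stats::approxfun(tt, ee, rule = 2)
  period <- curve$period
  function(t) f(t %% period)
}

#' Gaussian elastance closed form
#'
#' `E(t) = E_min + (E_max - E_min) * exp(-d^2 / (2 sigma^2))` with `d` the
#' circular distance from `t` to the peak time `t0` on a cycle of length
#' `period`.
#'
#' @param E_min,E_max Baseline and peak elastance (mmHg/ml, `E_max > E_min > 0`).
#' @param t0 Peak time (s), `sigma` Gaussian width (s), `period` cycle (s).
#' @return A periodic function of time.
#' @export
gaussian_elastance_function <- function(E_min, E_max, t0, sigma, period) {
  if (!(E_max > E_min && E_min > 0))
    stop("need E_max > E_min > 0", call. = FALSE)
  stopifnot(sigma > 0, period > 0)
  function(t) {
    d <- (t - t0) %% period
    d <- ifelse(d > period / 2, d - period, d)
    E_min + (E_max - E_min) * exp(-d^2 / (2 * sigma^2))
  }
}

#' Ventricular volume from outflow waveform
#'
#' Integrates the outflow (trapezoidal cumulative rule) and subtracts it from
#' the end-diastolic volume: `V(t) = EDV - int_0^t Q dtau`. Valid over the
#' ejection window (no inflow).
#'
#' @param time Uniform sample times (s).
#' @param flow Outflow waveform (ml/s).
#' @param EDV End-diastolic volume (ml, > 0).
#' @return Numeric volume samples (ml).
#' @export
volume_from_flow <- function(time, flow, EDV) {
  stopifnot(length(time) == length(flow), EDV > 0)
  V <- EDV - pracma::cumtrapz(time, flow)[, 1L]
  if (any(V <= 0))
    stop("flow integral exceeds the end-diastolic volume (V <= 0)",
         call. = FALSE)
  V
}

#' Align a pressure trace with a volume curve
#'
#' Shifts the volume/flow pair so that the ejection onset (first upcrossing
#' of flow above `flow_threshold_frac` of its peak) coincides with the
#' pressure upstroke landmark (first upcrossing of pressure above
#' `pressure_frac` of its range above the minimum). Both series must be
#' periodic samples of one cycle on a common uniform grid; the shift is
#' circular.
#'
#' @param time Uniform sample times covering one period (s).
#' @param pressure Ventricular pressure (mmHg).
#' @param volume Ventricular volume (ml).
#' @param flow Outflow waveform (ml/s) used for onset detection.
#' @param flow_threshold_frac Ejection-onset threshold, fraction of peak flow.
#' @param pressure_frac Pressure-landmark threshold, fraction of pressure range.
#' @return List with shifted `volume`, `flow`, the applied `lag_s` (positive:
#'   volume delayed) and the landmark times.
#' @export
align_pressure_volume <- function(time, pressure, volume, flow,
                                  flow_threshold_frac = 0.01,
                                  pressure_frac = 0.1) {
  n <- length(time)
  stopifnot(length(pressure) == n, length(volume) == n, length(flow) == n)
  if (diff(range(pressure)) <= .Machine$double.eps * max(abs(pressure), 1))
    stop("flat pressure trace: no detectable upstroke", call. = FALSE)
  thrQ <- flow_threshold_frac * max(flow)
  upQ <- which(flow > thrQ)
  if (!length(upQ) || max(flow) <= 0)
    stop("no detectable ejection onset in the flow waveform", call. = FALSE)
  iQ <- upQ[1L]
  thrP <- min(pressure) + pressure_frac * diff(range(pressure))
  upP <- which(pressure > thrP)
  if (!length(upP))
    stop("no detectable pressure upstroke", call. = FALSE)
  iP <- upP[1L]
  shift <- iP - iQ                      # samples to delay volume/flow by
  idx <- ((seq_len(n) - 1L - shift) %% n) + 1L
  dt <- if (n > 1) time[2L] - time[1L] else 0
  list(volume = volume[idx], flow = flow[idx], lag_s = shift * dt,
       ejection_onset_s = time[iQ], pressure_landmark_s = time[iP])
}

#' Systolic elastance from aligned pressure and volume
#'
#' Point-wise ratio `E(t) = P(t) / (V(t) - V0)` restricted to the window
#' where the outflow valve is open (flow above the detection threshold).
#'
#' @param time,pressure,volume,flow Aligned one-cycle samples.
#' @param V0 Unstressed volume (ml).
#' @param flow_threshold_frac Valve-open detection threshold, fraction of
#'   peak flow.
#' @return List with `idx` (sample indices of the systolic window), `time`,
#'   `E` (mmHg/ml).
#' @export
systolic_elastance <- function(time, pressure, volume, flow, V0 = 0,
                               flow_threshold_frac = 0.01) {
  n <- length(time)
  stopifnot(length(pressure) == n, length(volume) == n, length(flow) == n)
  thr <- flow_threshold_frac * max(flow)
  idx <- which(flow > thr)
  if (!length(idx)) stop("no systolic (valve-open) window detected",
                         call. = FALSE)
  idx <- seq(idx[1L], idx[length(idx)])  # contiguous window
  if (any(volume[idx] <= V0))
    stop("volume does not exceed the unstressed volume V0 in the systolic window",
         call. = FALSE)
  list(idx = idx, time = time[idx],
       E = pressure[idx] / (volume[idx] - V0))
}

#' Gaussian extrapolation of the systolic elastance
#'
#' Fits `E_g(t) = E_min + A * exp(-(t - t0)^2 / (2 sigma^2))` to the measured
#' systolic segment by Levenberg-Marquardt least squares and uses the fit to
#' fill the unmeasured part of the cycle; inside the measured window the data
#' are kept. The baseline is constrained to `E_min >= floor` (a pure Gaussian
#' decays to zero, which would make diastolic ventricular pressure vanish).
#'
#' @param time Full-cycle uniform grid (s) on `[0, period)`.
#' @param sys_idx Indices of the measured systolic window.
#' @param E_sys Elastance over the window (mmHg/ml).
#' @param period Cycle length (s).
#' @param floor Minimum admissible baseline elastance (mmHg/ml).
#' @return List with the full-cycle `E`, `segment` labels, and the fitted
#'   parameters `E_min`, `A`, `t0`, `sigma`.
#' @export
gaussian_extrapolate <- function(time, sys_idx, E_sys, period, floor = 0.05) {
  stopifnot(length(sys_idx) == length(E_sys), period > 0)
  ts <- time[sys_idx]
  start <- list(E_min = max(floor, min(E_sys) / 2),
                A = max(E_sys) - min(E_sys),
                t0 = ts[which.max(E_sys)],
                sigma = max(diff(range(ts)) / 4, 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      E ~ E_min + A * exp(-(t - t0)^2 / (2 * sigma^2)),
      data = data.frame(t = ts, E = E_sys), start = start,
      lower = c(E_min = floor, A = 1e-8, t0 = min(ts) - period,
                sigma = 1e-4),
      upper = c(E_min = max(E_sys), A = 10 * max(E_sys), t0 = max(ts) + period,
                sigma = 5 * period),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("Gaussian elastance fit failed to converge: ",
         conditionMessage(fit), call. = FALSE)
  cf <- as.list(stats::coef(fit))
  gf <- gaussian_elastance_function(cf$E_min, cf$E_min + cf$A,
                                    cf$t0 %% period, cf$sigma, period)
  E_full <- gf(time)
  segment <- rep("extrapolated", length(time))
  E_full[sys_idx] <- E_sys
  segment[sys_idx] <- "measured"
  rss <- sum(stats::resid(fit)^2)
  list(E = E_full, segment = segment, E_min = cf$E_min, A = cf$A,
       t0 = cf$t0 %% period, sigma = cf$sigma, rss = rss)
}

#' Fourier smoothing with peak preservation
#'
#' Truncates the discrete Fourier series of a periodic signal to
#' `n_harmonics` harmonics (infinitely differentiable, hence C1 as
#' required), then rescales the result so its maximum equals the
#' pre-smoothing maximum.
#'
#' @param E Uniform periodic samples.
#' @param n_harmonics Number of retained harmonics (>= 1, default 10).
#' @return Smoothed samples with the original peak value.
#' @export
fourier_smooth <- function(E, n_harmonics = 10) {
  if (!is.numeric(n_harmonics) || n_harmonics < 1)
    stop("n_harmonics must be >= 1", call. = FALSE)
  n <- length(E)
  H <- stats::fft(E)
  k <- seq_len(n) - 1L
  kk <- pmin(k, n - k)                 # harmonic index of each bin
  H[kk > n_harmonics] <- 0
  sm <- Re(stats::fft(H, inverse = TRUE)) / n
  sm * (max(E) / max(sm))
}

#' Build a patient-specific elastance curve
#'
#' Composition of the construction pipeline: outflow integration from EDV,
#' optional pressure-volume alignment, point-wise systolic elastance,
#' Gaussian extrapolation to the full cycle, Fourier smoothing and peak
#' rescaling. Inputs are one-cycle uniform samples.
#'
#' @param time Sample times (s) covering one cycle.
#' @param flow Outflow-valve flow (ml/s).
#' @param pressure Ventricular pressure (mmHg).
#' @param EDV End-diastolic volume (ml).
#' @param V0 Unstressed volume (ml, default 0: the construction divides
#'   pressure by the volume curve directly).
#' @param period Cycle length (s); default `max(time) + dt`.
#' @param n_harmonics Fourier truncation (default 10).
#' @param align Apply [align_pressure_volume()] before dividing (default
#'   `FALSE`: simultaneous recordings are already on a common clock).
#' @param floor Baseline elastance floor (mmHg/ml).
#' @return An [elastance_curve] with segment labels and, as attributes,
#'   the Gaussian fit parameters.
#' @export
build_elastance <- function(time, flow, pressure, EDV, V0 = 0,
                            period = NULL, n_harmonics = 10, align = FALSE,
                            floor = 0.05) {
  n <- length(time)
  stopifnot(length(flow) == n, length(pressure) == n)
  dt <- time[2L] - time[1L]
  if (is.null(period)) period <- time[n] - time[1L] + dt
  time <- time - time[1L]
  V <- volume_from_flow(time, pmax(flow, 0), EDV)
  if (align) {
    al <- align_pressure_volume(time, pressure, V, flow)
    V <- al$volume
    flow <- al$flow
  }
  sys <- systolic_elastance(time, pressure, V, flow, V0 = V0)
  ext <- gaussian_extrapolate(time, sys$idx, sys$E, period, floor = floor)
  E_sm <- fourier_smooth(ext$E, n_harmonics)
  curve <- elastance_curve(time, E_sm, period, segment = ext$segment, V0 = V0)
  attr(curve, "gaussian_fit") <- ext[c("E_min", "A", "t0", "sigma", "rss")]
  curve
}

#' Write / read an elastance curve as CSV
#'
#' Columns `time_s`, `E_mmHg_per_ml`, `segment`.
#'
#' @param curve An `elastance_curve`.
#' @param path Output file.
#' @return `write_elastance_csv` returns `path` invisibly;
#'   `read_elastance_csv` returns an `elastance_curve` (`period` is inferred
#'   from the grid).
#' @export
write_elastance_csv <- function(curve, path) {
  stopifnot(inherits(curve, "elastance_curve"))
  utils::write.csv(data.frame(time_s = curve$time,
                              E_mmHg_per_ml = curve$E,
                              segment = curve$segment),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_elastance_csv
#' @export
read_elastance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "E_mmHg_per_ml", "segment")
  if (!all(need %in% names(df)))
    stop("elastance CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  dt <- df$time_s[2L] - df$time_s[1L]
  elastance_curve(df$time_s, df$E_mmHg_per_ml,
                  period = df$time_s[nrow(df)] + dt - df$time_s[1L],
                  segment = df$segment)
}
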