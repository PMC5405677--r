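# Elastance construction pipeline: volume integration, alignment, pointwise
# division, Gaussian extrapolation, Fourier smoothing, end-to-end recovery.

test_that("volume_from_flow integrates the outflow from EDV", {
  tt <- seq(0, 0.2, by = 1e-3)
  V <- volume_from_flow(tt, rep(10, length(tt)), EDV = 40)
  expect_equal(V[length(V)], 38, tolerance = 1e-12)
  expect_true(all(diff(V) <= 0))
  # zero flow: identity
  expect_equal(volume_from_flow(tt, rep(0, length(tt)), 40),
               rep(40, length(tt)))
  # half-sine ejection with stroke volume 15 from EDV 38 -> ESV 23
  Tej <- 0.2
  A <- 15 * pi / (2 * Tej)
  V2 <- volume_from_flow(tt, A * sin(pi * tt / Tej), EDV = 38)
  expect_equal(V2[length(V2)], 23, tolerance = 1e-4)
  # integral exceeding EDV is a data error
  expect_error(volume_from_flow(tt, rep(300, length(tt)), EDV = 40),
               "exceeds")
})

test_that("pressure-volume alignment recovers a known lag", {
  period <- 0.5
  dt <- 1e-3
  tt <- seq(0, period - dt, by = dt)
  # pulses constructed so both landmark thresholds trip at the same sample
  pulse <- function(t, on, dur) ifelse(t >= on & t <= on + dur,
                                       sin(pi * (t - on) / dur), 0)
  Q <- 100 * pulse(tt, 0.10, 0.15)
  P <- 5 + 70 * pulse(tt, 0.10, 0.18)
  pfrac <- 0.012
  V <- volume_from_flow(tt, Q, EDV = 40)
  al0 <- align_pressure_volume(tt, P, V, Q, pressure_frac = pfrac)
  expect_equal(al0$lag_s, 0)
  # advance the flow/volume pair by 30 ms; alignment must delay them back
  lag <- 0.03
  k <- round(lag / dt)
  idx <- ((seq_along(tt) - 1L + k) %% length(tt)) + 1L
  al <- align_pressure_volume(tt, P, V[idx], Q[idx], pressure_frac = pfrac)
  expect_lt(abs(al$lag_s - lag), dt + 1e-12)
  expect_equal(al$volume, V)
  # flat pressure has no upstroke
  expect_error(align_pressure_volume(tt, rep(7, length(tt)), V, Q), "flat")
})

test_that("systolic elastance is the pointwise pressure-volume ratio", {
  tt <- seq(0, 0.1, by = 1e-3)
  n <- length(tt)
  expect_equal(systolic_elastance(tt, rep(80, n), rep(25, n),
                                  rep(10, n))$E[1L], 3.2)
  expect_equal(systolic_elastance(tt, rep(60, n), rep(35, n), rep(10, n),
                                  V0 = 15)$E[1L], 3.0)
  expect_error(systolic_elastance(tt, rep(60, n), rep(10, n), rep(10, n),
                                  V0 = 15), "V0")
  # exact round trip from a known elastance, noise-free
  Efun <- gaussian_elastance_function(0.3, 2.5, 0.05, 0.03, 0.4)
  V <- seq(40, 25, length.out = n)
  P <- Efun(tt) * V
  out <- systolic_elastance(tt, P, V, rep(10, n))
  expect_lt(max(abs(out$E - Efun(tt)) / Efun(tt)), 1e-9)
})

test_that("gaussian extrapolation recovers generating parameters", {
  period <- 0.46
  tt <- seq(0, period, length.out = 461)[1:460]
  truth <- list(E_min = 0.25, A = 2.6, t0 = 0.16, sigma = 0.05)
  gf <- gaussian_elastance_function(truth$E_min, truth$E_min + truth$A,
                                    truth$t0, truth$sigma, period)
  win <- which(tt > 0.08 & tt < 0.26)
  fit <- gaussian_extrapolate(tt, win, gf(tt[win]), period)
  for (k in c("E_min", "A", "t0", "sigma"))
    expect_lt(abs(fit[[k]] - truth[[k]]) / truth[[k]], 1e-3)
  expect_identical(unique(fit$segment[win]), "measured")
  expect_identical(unique(fit$segment[-win]), "extrapolated")
  # symmetric segment: fitted centre at the segment's maximum
  expect_lt(abs(fit$t0 - tt[win][which.max(gf(tt[win]))]), 1e-3)
  # full-period window: output equals input everywhere
  all_idx <- seq_along(tt)
  fit2 <- gaussian_extrapolate(tt, all_idx, gf(tt), period)
  expect_equal(fit2$E, gf(tt))
})

test_that("fourier smoothing is band-limit exact, peak-preserving, idempotent", {
  n <- 512
  th <- 2 * pi * seq_len(n) / n
  # pure first harmonic passes through unchanged
  x1 <- 2 + cos(th)
  expect_lt(max(abs(fourier_smooth(x1, 1) - x1)), 1e-9)
  # peak preservation on an arbitrary signal
  set.seed(42)
  x2 <- 3 + cos(th) + 0.4 * sin(3 * th) + 0.1 * stats::rnorm(n)
  expect_lt(abs(max(fourier_smooth(x2, 10)) - max(x2)) / max(x2), 1e-6)
  # a C0 kink violates the band-limit curvature bound; smoothing restores it
  kink <- pmax(1 - abs(th - pi), 0.2)
  sm <- fourier_smooth(kink, 10)
  expect_gt(max_slope_jump(kink, 1), c1_bound(kink, 1, 10))
  expect_lt(max_slope_jump(sm, 1), c1_bound(sm, 1, 10))
  # idempotence after the first rescale
  once <- fourier_smooth(x2, 10)
  twice <- fourier_smooth(once, 10)
  expect_lt(max(abs(twice - once)) / max(once), 1e-9)
  expect_error(fourier_smooth(x2, 0), "n_harmonics")
})

test_that("the pipeline recovers a known elastance from virtual recordings", {
  truth <- gen_elastance_truth()
  tf <- attr(truth, "truth_fun")
  vp <- gen_patient_waveforms(truth, noise_sigma = 0, seed = 1)
  curve <- build_elastance(vp$time, vp$flow, vp$pressure, EDV = vp$EDV,
                           V0 = vp$V0)
  Etrue <- tf(curve$time)
  rms <- sqrt(mean(((curve$E - Etrue) / Etrue)^2))
  expect_lt(rms, 0.02)
  expect_lt(abs(curve$peak - max(Etrue)) / max(Etrue), 0.02)
  # peak time within 2 samples of the truth
  dt <- curve$time[2L] - curve$time[1L]
  expect_lte(abs(curve$time[which.max(curve$E)] -
                 attr(truth, "truth_params")$t0), 2 * dt)
  # ElastanceCurve invariants: positive, periodic closure, C1
  expect_true(all(curve$E > 0))
  ef <- elastance_function(curve)
  expect_lt(abs(ef(0) - ef(curve$period)), 1e-9)
  expect_lt(max_slope_jump(curve$E, curve$period),
            c1_bound(curve$E, curve$period, 10))
  # an EDV smaller than the ejected volume is a data error
  expect_error(build_elastance(vp$time, vp$flow, vp$pressure,
                               EDV = 0.5 * vp$stroke_volume), "exceeds")
})
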