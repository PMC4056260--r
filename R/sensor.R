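#' Synthetic continuous glucose monitor state
#'
#' Models the FreeStyle-Navigator-style subcutaneous sensor channel: a
#' first-order blood-to-interstitial lag (default time constant 15 min), a
#' multiplicative calibration gain that drifts linearly between one-point
#' recalibrations, additive Gaussian reading noise, a 1-hour warm-up during
#' which no readings are produced, and a display floor of 1.1 mM.
#'
#' @param t_start sensor start (insertion) time, min.
#' @param lag_tau blood-to-interstitial lag time constant, min.
#' @param noise_sd additive reading noise SD, mM.
#' @param drift_rate calibration-gain drift, per hour.
#' @param cal_gain initial calibration gain (clamped to \[0.7, 1.3\]).
#' @param cal_offset calibration offset, mM (one-point calibration keeps
#'   this at 0).
#' @param G_isf initial interstitial glucose, mM (`NA`: set on first step).
#' @param warmup warm-up duration, min.
#' @return An object of class `sensor_state`.
#' @export
sensor_state <- function(t_start = 0, lag_tau = 15, noise_sd = 0.45,
                         drift_rate = 0.005, cal_gain = 1, cal_offset = 0,
                         G_isf = NA_real_, warmup = 60) {
  if (lag_tau <= 0) stop("lag_tau must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(G_isf = G_isf, cal_gain = clamp(cal_gain, 0.7, 1.3),
                 cal_offset = cal_offset, t_start = t_start, t = t_start,
                 last_cal_t = NA_real_, noise_sd = noise_sd,
                 lag_tau = lag_tau, drift_rate = drift_rate,
                 warmup = warmup, roc = 0), class = "sensor_state")
}

#' Advance the sensor lag compartment
#'
#' Integrates `dG_isf/dt = (plasma_G - G_isf)/lag_tau` exactly over `dt`
#' (plasma held constant across the step) and applies the linear gain
#' drift.
#'
#' @param s a [sensor_state()].
#' @param plasma_G current plasma glucose, mM (> 0).
#' @param dt step, min.
#' @return The advanced `sensor_state`.
#' @export
sensor_step <- function(s, plasma_G, dt = 1) {
  if (!is.finite(plasma_G) || plasma_G <= 0)
    stop("plasma_G must be positive")
  if (is.na(s$G_isf)) s$G_isf <- plasma_G
  a <- exp(-dt / s$lag_tau)
  old <- s$G_isf
  s$G_isf <- plasma_G + (s$G_isf - plasma_G) * a
  ## smoothed rate of change, mM/min (used to defer calibration during
  ## rapid glucose flux)
  s$roc <- 0.8 * s$roc + 0.2 * (s$G_isf - old) / dt
  s$cal_gain <- clamp(s$cal_gain + s$drift_rate * dt / 60, 0.7, 1.3)
  s$t <- s$t + dt
  s
}

#' Read the sensor
#'
#' Returns `NA` while the sensor is warming up (first hour after start) or
#' flagged unavailable; otherwise
#' `cal_gain * G_isf + cal_offset + N(0, noise_sd)`, floored at the display
#' minimum of 1.1 mM. Consumes one draw from the R random stream when a
#' value is produced and `noise_sd > 0`.
#'
#' @param s a [sensor_state()].
#' @param available logical override for dropouts (default `TRUE`).
#' @return Sensor glucose, mM, or `NA_real_`.
#' @export
sensor_read <- function(s, available = TRUE) {
  if (!available || is.na(s$G_isf) || (s$t - s$t_start) < s$warmup)
    return(NA_real_)
  val <- s$cal_gain * s$G_isf + s$cal_offset
  if (s$noise_sd > 0) val <- val + rnorm(1, 0, s$noise_sd)
  max(1.1, val)
}

#' One-point sensor recalibration
#'
#' Resets the calibration gain so that the immediate post-calibration
#' (noise-free) reading equals the reference value; the offset stays 0 and
#' the interstitial (physiological) state is untouched. The gain is
#' clamped to \[0.7, 1.3\].
#'
#' @param s a [sensor_state()].
#' @param reference_G reference (arterial) glucose, mM, in \[1, 40\].
#' @param t calibration time, min.
#' @return The recalibrated `sensor_state`.
#' @export
sensor_calibrate <- function(s, reference_G, t = s$t) {
  if (!is.finite(reference_G) || reference_G < 1 || reference_G > 40)
    stop("reference_G must lie in [1, 40] mM")
  if (is.na(s$G_isf) || s$G_isf <= 0)
    stop("cannot calibrate before the lag compartment is initialized")
  s$cal_gain <- clamp(reference_G / s$G_isf, 0.7, 1.3)
  s$last_cal_t <- t
  s
}

#' Reference (arterial) glucose sample
#'
#' Plasma glucose plus blood-gas-analyzer noise (Gaussian, default SD
#' 0.1 mM), floored at 0.1 mM.
#'
#' @param plasma_G plasma glucose, mM (> 0).
#' @param sd analyzer noise SD, mM.
#' @return Measured reference glucose, mM.
#' @export
reference_sample <- function(plasma_G, sd = 0.1) {
  if (!is.finite(plasma_G) || plasma_G <= 0)
    stop("plasma_G must be positive")
  max(0.1, plasma_G + if (sd > 0) rnorm(1, 0, sd) else 0)
}

#' Sample sensor dropout windows
#'
#' Poisson-arriving outages (default one per 24 h on average) with
#' lognormal durations (median 10 min), emulating the order of magnitude
#' of reported sensor unavailability.
#'
#' @param duration_min simulated period, min.
#' @param rate_per_day expected outages per 24 h.
#' @param dur_meanlog,dur_sdlog lognormal duration parameters (min).
#' @return Data frame with columns `start`, `end` (min), possibly empty.
#' @export
make_dropout_windows <- function(duration_min, rate_per_day = 1,
                                 dur_meanlog = log(10), dur_sdlog = 0.5) {
  starts <- numeric(0)
  t <- 0
  rate_per_min <- rate_per_day / 1440
  if (rate_per_min > 0) {
    repeat {
      t <- t + rexp(1, rate_per_min)
      if (t > duration_min) break
      starts <- c(starts, t)
    }
  }
  if (!length(starts))
    return(data.frame(start = numeric(0), end = numeric(0)))
  durs <- rlnorm(length(starts), dur_meanlog, dur_sdlog)
  data.frame(start = starts, end = pmin(starts + durs, duration_min))
}

## TRUE where t falls inside any dropout window
in_dropout <- function(t, windows) {
  if (!nrow(windows)) return(rep(FALSE, length(t)))
  vapply(t, function(tt) any(tt >= windows$start & tt < windows$end),
         logical(1))
}

#' Simulate 48 h of sensor error against a wavy plasma trace
#'
#' Utility used to tune and verify sensor accuracy: runs the sensor at
#' 1-min steps against a smooth plasma profile oscillating in the 6--11 mM
#' band, recalibrates every `cal_every` minutes against noisy references,
#' and returns the accuracy metrics of hourly reference samples versus the
#' paired sensor readings (see [sensor_accuracy()]).
#'
#' @param noise_sd,drift_rate sensor error parameters.
#' @param hours simulated duration.
#' @param cal_every recalibration interval, min.
#' @param seed RNG seed for noise realizations.
#' @return List with elements `mad`, `mard`, `pct_within20`.
#' @export
simulate_sensor_error <- function(noise_sd, drift_rate = 0.005, hours = 48,
                                  cal_every = 180, seed = 1) {
  set.seed(seed)
  n_min <- hours * 60
  plasma <- function(t) 8.5 + 2 * sin(2 * pi * t / 600) +
    0.8 * sin(2 * pi * t / 173)
  s <- sensor_state(noise_sd = noise_sd, drift_rate = drift_rate,
                    cal_gain = clamp(rnorm(1, 1, 0.05), 0.7, 1.3),
                    G_isf = plasma(0))
  sens <- data.frame(t = numeric(0), G = numeric(0))
  refs <- data.frame(t = numeric(0), G = numeric(0))
  for (t in seq_len(n_min)) {
    s <- sensor_step(s, plasma(t), dt = 1)
    if (t %% cal_every == 0)
      s <- sensor_calibrate(s, reference_sample(plasma(t)), t = t)
    if (t %% 60 == 0) {
      refs <- rbind(refs, data.frame(t = t, G = reference_sample(plasma(t))))
      v <- sensor_read(s)
      if (!is.na(v)) sens <- rbind(sens, data.frame(t = t, G = v))
    }
  }
  sensor_accuracy(sens, refs)
}

#' Tune sensor noise to a target MARD
#'
#' Bisects on `noise_sd` until the simulated 48-h median relative absolute
#' deviation (MARD) of the synthetic sensor matches `target_mard`. Each
#' candidate is evaluated with the same seed (common random numbers), so
#' the simulated MARD is monotone in `noise_sd` and bisection converges.
#'
#' @param target_mard target MARD, percent.
#' @param drift_rate gain drift held fixed during tuning, per hour.
#' @param interval search interval for `noise_sd`, mM.
#' @param tol bisection tolerance on MARD, percentage points.
#' @param seed RNG seed used for every evaluation.
#' @return List with `noise_sd` (mM) and the achieved `mard` (%).
#' @export
tune_sensor_noise <- function(target_mard = 7, drift_rate = 0.005,
                              interval = c(0.01, 2), tol = 0.1, seed = 1) {
  f <- function(sd) simulate_sensor_error(sd, drift_rate, seed = seed)$mard
  lo <- interval[1]; hi <- interval[2]
  if (f(lo) > target_mard) stop("target MARD below the drift-only floor")
  if (f(hi) < target_mard) stop("target MARD not reachable within interval")
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    m <- f(mid)
    if (abs(m - target_mard) < tol) return(list(noise_sd = mid, mard = m))
    if (m < target_mard) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  list(noise_sd = mid, mard = f(mid))
}
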