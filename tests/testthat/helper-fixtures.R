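## Shared fixtures, built once per test session.

## nominal virtual patient calibrated to 10.4 mM at 1.5 U/h basal under
## 7.5 g/h feeding (sensitivities rescaled like make_cohort does)
nominal_test_patient <- function(G0 = 10.4, u0 = 1.5, CHO = 7.5) {
  p <- patient_params()
  m <- glucoloop:::solve_sensitivity_scale(p, G0, u0, CHO)
  p$S_IT <- p$S_IT * m
  p$S_ID <- p$S_ID * m
  p$S_IE <- p$S_IE * m
  p$G_entry <- G0
  p$basal_insulin <- u0
  p$calib_CHO <- CHO
  p
}

## constant-feeding scenario without disturbances
quiet_scenario <- function(duration_h = 48, CHO = 7.5) {
  make_scenario(seed = 1, duration_h = duration_h,
                config = scenario_config(CHO_mean = CHO, CHO_sd = 0,
                                         max_interruptions_per_day = 0,
                                         steroid_prob = 0))
}

## memoized noise-free 48-h closed-loop run on the nominal patient
local_cache <- new.env(parent = emptyenv())

deterministic_cl_record <- function() {
  if (is.null(local_cache$det_cl)) {
    local_cache$det_cl <- simulate_subject(
      nominal_test_patient(), "CL", quiet_scenario(), seed = 1,
      sensor_args = list(noise_sd = 0, drift_rate = 0),
      dropout_rate_per_day = 0, ref_noise_sd = 0, sensor_gain_sd = 0)
  }
  local_cache$det_cl
}

## memoized nominal 12 + 12 trial under default configuration
acceptance_trial <- function(seed = 1) {
  key <- paste0("trial_", seed)
  if (is.null(local_cache[[key]]))
    local_cache[[key]] <- run_trial(n_per_arm = 12, seed = seed)
  local_cache[[key]]
}

## independent Euler integrator over the same model equations, written
## directly from the formulas (oracle for the RK4 path)
euler_oracle <- function(p, s0, u, dex, cho, r, dt, n_min) {
  s <- s0
  steps <- as.integer(round(n_min / dt))
  out <- numeric(n_min + 1)
  vgw <- p$V_G * p$weight
  out[1] <- s[1] / vgw
  per_out <- as.integer(round(1 / dt))
  for (k in seq_len(steps)) {
    G <- s[1] / vgw
    f01c <- p$F01 * p$weight * min(1, G / 4.5)
    egp <- p$EGP0 * p$weight * max(0, 1 - s[6])
    ra <- 5.551 * s[7] / p$gut_tau + dex * 0.2 * 5.551 / 60
    d <- c(-f01c - s[4] * s[1] + p$k12 * s[2] + egp + ra,
           s[4] * s[1] - (p$k12 + s[5]) * s[2],
           u * 1000 / 60 / (p$V_I * p$weight) - p$k_e * s[3],
           -p$k_a1 * s[4] + p$k_a1 * p$S_IT * r * s[3],
           -p$k_a2 * s[5] + p$k_a2 * p$S_ID * r * s[3],
           -p$k_a3 * s[6] + p$k_a3 * p$S_IE * r * s[3],
           cho / 60 - s[7] / p$gut_tau)
    s <- pmax(s + dt * d, 0)
    if (k %% per_out == 0) out[k / per_out + 1] <- s[1] / vgw
  }
  out
}
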