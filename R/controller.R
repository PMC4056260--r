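#' Controller configuration
#'
#' Tunables of the adaptive model-predictive dosing algorithm. Every five
#' minutes the controller assimilates the latest sensor (or fallback
#' reference) glucose into an internal copy of the compartment model,
#' adapts two parameters -- a rapidly changing glucose-flux correction
#' `F_c` and a slowly changing estimate `b_est` of the insulin rate that
#' maintains euglycemia -- and then either optimizes the insulin rate over
#' a 90-min prediction horizon or, at low predicted glucose, doses 20%
#' dextrose from a 40-min horizon.
#'
#' @param G_target glucose setpoint, mM (midpoint of the 6.0--8.0 mM
#'   target band).
#' @param horizon_insulin insulin prediction horizon, min.
#' @param horizon_dextrose dextrose prediction horizon, min.
#' @param lambda_u insulin-move penalty; the default makes a 1 U/h rate
#'   change cost as much as a sustained 0.3 mM offset over the insulin
#'   horizon (18 grid points x 0.3^2).
#' @param tau_f decay time constant of the flux correction `F_c`, min.
#' @param k_b integral gain of `b_est`, U/h per mM of innovation per min;
#'   the default gives `b_est` an effective adaptation time of a few
#'   hours.
#' @param state_gain fraction of the glucose innovation applied directly
#'   to the internal model's accessible glucose mass at each assimilation
#'   (observer correction in \[0, 1\]).
#' @param suspend_offset insulin is withheld when observed glucose is at
#'   or below `G_target - suspend_offset`, mM.
#' @param G_rescue predicted-glucose threshold triggering dextrose, mM.
#' @param K_d dextrose dosing gain, mL/h per mM of predicted shortfall.
#' @param u_b_mult aggressiveness limit: the insulin command may not
#'   exceed `max(2, u_b_mult * b_est)` U/h, tying dose escalation to the
#'   adaptive basal estimate.
#' @param insulin_cap maximal insulin rate, U/h.
#' @param dex_cap maximal 20% dextrose rate, mL/h.
#' @param u_step insulin optimization grid step, U/h.
#' @param u_coarse coarse pre-scan step for the optimizer, U/h.
#' @param b_prior_per_kg weight-based prior for `b_est`, U/kg/h.
#' @param fallback_mult cap on the insulin command, as a multiple of
#'   `b_est`, while dosing on fallback reference values (warm-up,
#'   dropouts): without continuous feedback the controller stays close to
#'   the basal estimate.
#' @param fall_guard_slow,fall_guard_fast observed fall-rate thresholds,
#'   mM/min: while glucose falls faster than `fall_guard_slow` the insulin
#'   command may not escalate above the previous command (or `b_est` if
#'   lower was commanded); faster than `fall_guard_fast`, it is capped at
#'   half the basal estimate.
#' @param lag_comp sensor-lag compensation horizon, min: the low-glucose
#'   rules (insulin suspend, dextrose rescue) act on
#'   `G_obs + lag_comp * trend` when glucose is falling, anticipating the
#'   blood-to-sensor lag.
#' @param background_CHO fixed population prior for background glucose
#'   appearance carried by the internal model, g/h carbohydrate
#'   equivalent. This is a modeling constant, not measured nutrition: the
#'   algorithm receives no information about actual enteral or parenteral
#'   feeding, and the flux correction `F_c` absorbs the difference.
#' @param cycle_min control cycle length, min.
#' @return A list of class `controller_config`.
#' @export
controller_config <- function(G_target = 7.0, horizon_insulin = 90,
                              horizon_dextrose = 40, lambda_u = 5,
                              tau_f = 30, k_b = 5e-3, state_gain = 0.6,
                              suspend_offset = 1.2, G_rescue = 4.5,
                              K_d = 200, u_b_mult = 3, insulin_cap = 50, dex_cap = 200,
                              u_step = 0.05, u_coarse = 0.5,
                              fall_guard_slow = 0.06, fall_guard_fast = 0.12,
                              fallback_mult = 1.25, lag_comp = 15,
                              b_prior_per_kg = 0.02, background_CHO = 7.5,
                              cycle_min = 5) {
  cfg <- as.list(environment())
  if (G_target < 5 || G_target > 10) stop("G_target must lie in [5, 10] mM")
  if (horizon_insulin <= 0 || horizon_dextrose <= 0)
    stop("prediction horizons must be positive")
  class(cfg) <- "controller_config"
  cfg
}

#' Initialize the controller
#'
#' Builds the controller state from the patient's weight and a reference
#' glucose value, the only patient-specific information the algorithm
#' receives. The internal model uses nominal (population) parameters at
#' the patient's weight; its state is set to the equilibrium consistent
#' with the reference glucose, `F_c` starts at zero, and `b_est` starts at
#' the weight-based prior (0.02 U/kg/h).
#'
#' @param weight patient weight, kg.
#' @param reference_G initializing reference glucose, mM, in \[1, 40\].
#' @param config a [controller_config()].
#' @return An object of class `controller_state`.
#' @export
controller_init <- function(weight, reference_G,
                            config = controller_config()) {
  if (weight <= 0) stop("weight must be positive")
  if (!is.finite(reference_G) || reference_G < 1 || reference_G > 40)
    stop("reference_G must lie in [1, 40] mM")
  pop <- patient_params(weight = weight)
  u_nom <- insulin_for_glucose(pop, config$G_target,
                               CHO = config$background_CHO)
  b_est <- config$b_prior_per_kg * weight
  m_int <- u_nom / max(b_est, 0.1)
  u_ref <- insulin_for_glucose(pop, reference_G,
                               CHO = config$background_CHO,
                               resistance = m_int)
  st <- steady_state_glucose(pop, u_ref, CHO = config$background_CHO,
                             resistance = m_int, full = TRUE)
  cs <- list(params_int = pop, pvec = param_vec(pop),
             state_int = state_vec(st), F_c = 0, b_est = b_est,
             u_nom = u_nom, u_prev = 0, dex_prev = 0,
             G_target = config$G_target, last_obs = reference_G,
             last_dev = 10, last_cal_t = 0, next_cal_due = 60,
             trend = 0, mode = "fallback", t = 0, config = config)
  class(cs) <- "controller_state"
  cs
}

## Internal-model sensitivity scale: b_est is, by construction, the rate
## at which the scaled internal model sits in steady state at G_target.
internal_scale <- function(cs) cs$u_nom / max(cs$b_est, 0.1)

## lag-compensated observation for the low-glucose safety rules: project
## the observed level forward by the sensor lag when glucose is falling
effective_obs <- function(cs) {
  cs$last_obs + cs$config$lag_comp * min(cs$trend, 0)
}

#' Internal-model glucose estimate
#'
#' @param cs a `controller_state`.
#' @return Current internal-model plasma glucose, mM.
#' @export
internal_glucose <- function(cs) {
  cs$state_int[1] / (cs$params_int$V_G * cs$params_int$weight)
}

#' Assimilate an observation
#'
#' Advances the internal model by `dt` minutes under the previously
#' commanded insulin and dextrose with `F_c` as additional glucose flux,
#' then updates the two adaptive parameters from the innovation
#' `e = G_obs - G_model`: `F_c` is a leaky fast integrator
#' (`F_c <- exp(-dt/tau_f) F_c + K_f e`, effective time constant
#' `tau_f` = 30 min) and `b_est` accumulates `k_b * e * dt`, clamped to
#' \[0, 50\] U/h. Finally the observer correction moves the internal
#' glucose mass a fraction `state_gain` of the innovation toward the
#' observation, so predictions start from the assimilated glucose level.
#'
#' @param cs a `controller_state`.
#' @param G_obs observed glucose, mM (sensor or fallback reference).
#' @param dt minutes since the previous assimilation.
#' @return The updated `controller_state`.
#' @export
ctrl_assimilate <- function(cs, G_obs, dt = 5) {
  if (!is.finite(G_obs) || G_obs <= 0)
    stop("non-finite or non-positive observation")
  cfg <- cs$config
  cs$state_int <- as.numeric(cpp_advance(
    cs$state_int, cs$pvec, cs$u_prev, cs$dex_prev, cfg$background_CHO,
    internal_scale(cs), cs$F_c, 1, as.integer(dt)))
  e <- G_obs - internal_glucose(cs)
  lam <- exp(-dt / cfg$tau_f)
  K_f <- (1 - lam) * cs$params_int$V_G * cs$params_int$weight / cfg$tau_f
  cs$F_c <- lam * cs$F_c + K_f * e
  cs$b_est <- clamp(cs$b_est + cfg$k_b * e * dt, 0, 50)
  vgw <- cs$params_int$V_G * cs$params_int$weight
  cs$state_int[1] <- max(0, cs$state_int[1] + cfg$state_gain * e * vgw)
  cs$last_obs <- G_obs
  cs$t <- cs$t + dt
  cs
}

#' Predict glucose under a constant insulin rate
#'
#' Forward-simulates the internal model (current `F_c` and `b_est`
#' context, no nutrition input) at a constant insulin rate on a 5-min
#' grid.
#'
#' @param cs a `controller_state`.
#' @param u constant insulin rate, U/h (>= 0).
#' @param horizon horizon, min (default: the insulin horizon).
#' @return Numeric vector of predicted plasma glucose, mM, at
#'   5, 10, ..., `horizon` minutes ahead.
#' @export
ctrl_predict <- function(cs, u, horizon = cs$config$horizon_insulin) {
  if (horizon <= 0) stop("horizon must be positive")
  if (u < 0) stop("u must be non-negative")
  n <- max(1L, as.integer(round(horizon / 5)))
  as.numeric(cpp_predict_glucose(cs$state_int, cs$pvec, u,
                                 cs$config$background_CHO,
                                 internal_scale(cs), cs$F_c, 5, n))
}

#' Optimize the insulin rate
#'
#' Minimizes
#' `J(u) = sum_k (G_k(u) - G_target)^2 + lambda_u (u - u_prev)^2`
#' over the candidate grid `u = 0, 0.05, ..., 50` U/h with predictions
#' over the 90-min horizon. The default search scans a 0.5 U/h coarse grid
#' and refines at 0.05 U/h around the coarse optimum; `exhaustive = TRUE`
#' evaluates the full fine grid. The suspend safety rule returns 0 U/h
#' outright (attribute `"suspended"`) whenever the last observed glucose
#' is at or below `G_target - suspend_offset` (i.e. more than 1.2 mM below
#' target).
#'
#' @param cs a `controller_state`.
#' @param exhaustive evaluate the complete fine grid instead of
#'   coarse-to-fine search.
#' @return Insulin rate, U/h, in \[0, 50\], with logical attribute
#'   `"suspended"`.
#' @export
compute_insulin <- function(cs, exhaustive = FALSE) {
  cfg <- cs$config
  if (min(cs$last_obs, effective_obs(cs)) <= cs$G_target - cfg$suspend_offset)
    return(structure(0, suspended = TRUE))
  n <- as.integer(round(cfg$horizon_insulin / 5))
  r <- internal_scale(cs)
  cost <- function(grid) cpp_insulin_cost(cs$state_int, cs$pvec, grid,
                                          cfg$background_CHO, r, cs$F_c,
                                          cs$G_target, cfg$lambda_u,
                                          cs$u_prev, 5, n)
  if (exhaustive) {
    grid <- seq(0, cfg$insulin_cap, by = cfg$u_step)
    u <- grid[which.min(cost(grid))]
  } else {
    coarse <- seq(0, cfg$insulin_cap, by = cfg$u_coarse)
    u0 <- coarse[which.min(cost(coarse))]
    fine <- seq(max(0, u0 - cfg$u_coarse),
                min(cfg$insulin_cap, u0 + cfg$u_coarse), by = cfg$u_step)
    u <- fine[which.min(cost(fine))]
  }
  ## predictive feasibility: predicted glucose under the chosen rate must
  ## stay above the suspend level over the whole horizon; otherwise back
  ## off to the largest feasible rate (prediction is monotone in u)
  floor_G <- cs$G_target - cfg$suspend_offset
  pred_min <- function(uu) min(ctrl_predict(cs, uu, cfg$horizon_insulin))
  if (u > 0 && pred_min(u) < floor_G) {
    lo <- 0; hi <- u
    for (i in 1:20) {
      mid <- (lo + hi) / 2
      if (pred_min(mid) < floor_G) hi <- mid else lo <- mid
    }
    u <- floor(lo / cfg$u_step) * cfg$u_step
  }
  structure(clamp(u, 0, cfg$insulin_cap), suspended = FALSE)
}

#' Compute the rescue dextrose rate
#'
#' Predicts glucose at zero insulin over the 40-min dextrose horizon; if
#' the predicted minimum falls below the rescue threshold (4.5 mM), doses
#' 20% dextrose proportionally to the shortfall (`K_d` = 100 mL/h per
#' mM), capped at 200 mL/h. A positive dextrose command always forces the
#' insulin command to zero.
#'
#' @param cs a `controller_state`.
#' @return Dextrose rate, mL/h, in \[0, 200\].
#' @export
compute_dextrose <- function(cs) {
  cfg <- cs$config
  g_min <- min(ctrl_predict(cs, 0, cfg$horizon_dextrose), cs$last_obs,
               effective_obs(cs))
  if (g_min >= cfg$G_rescue) return(0)
  clamp(cfg$K_d * (cfg$G_rescue - g_min), 0, cfg$dex_cap)
}

#' Schedule the next reference-glucose request
#'
#' The algorithm requests a reference measurement every 1 to 6 hours
#' depending on the relative deviation between sensor and reference at the
#' last calibration: deviations of 2% or less map to 360 min, 20% or more
#' to 60 min, linear in between. At sensor glucose below 3.5 mM the
#' request interval is 30 min regardless of deviation.
#'
#' @param sensor_G current sensor glucose, mM (`NA` treated as not-low).
#' @param deviation_pct last relative sensor-reference deviation, percent
#'   (>= 0).
#' @return Minutes until the next reference request.
#' @export
schedule_calibration <- function(sensor_G, deviation_pct) {
  if (deviation_pct < 0) stop("deviation_pct must be non-negative")
  if (!is.na(sensor_G) && sensor_G < 3.5) return(30)
  clamp(360 - (deviation_pct - 2) * 300 / 18, 60, 360)
}

#' Run one 5-minute control cycle
#'
#' Assimilates the sensor reading (or, when the sensor is unavailable, the
#' latest reference value carried forward), computes the dextrose and
#' insulin commands under the safety rules (insulin capped at 50 U/h,
#' dextrose at 200 mL/h, never both nonzero, insulin suspended more than
#' 1.2 mM below target), and schedules the next reference request.
#'
#' @param cs a `controller_state` whose clock `cs$t` is on the 5-min grid.
#' @param t current time, min; must equal `cs$t` and lie on the grid.
#' @param sensor_G sensor glucose, mM, or `NA` if unavailable.
#' @param reference_G latest reference glucose, mM (zero-order hold).
#' @return List with the updated `controller_state` (`cs`) and a one-row
#'   data frame `command` with columns `t_min`, `basis`, `insulin_Uh`,
#'   `dextrose_mLh`, `internal_G_mM`, `F_c`, `b_est`, `next_cal_due`.
#' @export
control_cycle <- function(cs, t, sensor_G, reference_G) {
  cfg <- cs$config
  if (t %% cfg$cycle_min != 0 || t != cs$t)
    stop("control_cycle called off the 5-min grid")
  if (is.na(sensor_G)) {
    basis <- "fallback"
    G_obs <- reference_G
  } else {
    basis <- "sensor"
    G_obs <- sensor_G
  }
  cs$mode <- basis
  ## smoothed observed glucose trend, mM/min
  cs$trend <- 0.6 * cs$trend + 0.4 * (G_obs - cs$last_obs) / cfg$cycle_min
  cs <- ctrl_assimilate(cs, G_obs, dt = cfg$cycle_min)
  dex <- compute_dextrose(cs)
  ins <- if (dex > 0) 0 else as.numeric(compute_insulin(cs))
  ## without live sensor feedback, dose conservatively: never above the
  ## current euglycemia-maintaining estimate
  if (basis == "fallback") ins <- min(ins, cfg$fallback_mult * cs$b_est)
  ## no escalation while glucose is falling rapidly
  if (cs$trend < -cfg$fall_guard_fast) {
    ins <- min(ins, cs$b_est / 2)
  } else if (cs$trend < -cfg$fall_guard_slow) {
    ins <- min(ins, max(cs$u_prev, cs$b_est))
  }
  ins <- min(ins, max(2, cfg$u_b_mult * cs$b_est))
  ins <- clamp(ins, 0, cfg$insulin_cap)
  dex <- clamp(dex, 0, cfg$dex_cap)
  cs$u_prev <- ins
  cs$dex_prev <- dex
  interval <- schedule_calibration(sensor_G, cs$last_dev)
  cs$next_cal_due <- cs$last_cal_t + interval
  cmd <- data.frame(t_min = t, basis = basis, insulin_Uh = ins,
                    dextrose_mLh = dex, internal_G_mM = internal_glucose(cs),
                    F_c = cs$F_c, b_est = cs$b_est,
                    next_cal_due = cs$next_cal_due,
                    stringsAsFactors = FALSE)
  list(cs = cs, command = cmd)
}

#' Replay a logged glucose series through the controller
#'
#' Deterministically re-runs the dosing algorithm against a logged time
#' series of sensor and reference glucose, emitting the command log. The
#' input needs columns `t` (min, on the 5-min grid starting at 0),
#' `sensor` (mM, `NA` when unavailable) and `reference` (mM, `NA` between
#' samples; carried forward).
#'
#' @param df data frame as described, or a path to a CSV file.
#' @param weight patient weight, kg.
#' @param config a [controller_config()].
#' @return The command-log data frame (one row per 5-min cycle).
#' @export
replay_controller <- function(df, weight, config = controller_config()) {
  if (is.character(df)) df <- utils::read.csv(df)
  stopifnot(all(c("t", "sensor", "reference") %in% names(df)))
  df <- df[order(df$t), ]
  ref0 <- df$reference[!is.na(df$reference)][1]
  if (is.na(ref0)) stop("replay input contains no reference value")
  cs <- controller_init(weight, ref0, config)
  ref_hold <- ref0
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    t <- df$t[i]
    if (!is.na(df$reference[i])) ref_hold <- df$reference[i]
    step <- control_cycle(cs, t, df$sensor[i], ref_hold)
    cs <- step$cs
    out[[i]] <- step$command
  }
  do.call(rbind, out)
}
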