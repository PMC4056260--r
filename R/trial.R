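#' Scenario configuration
#'
#' @param CHO_mean,CHO_sd Gaussian continuous enteral carbohydrate rate,
#'   g/h (clamped at 0).
#' @param max_interruptions_per_day feeding interruptions per 24 h are
#'   drawn uniformly from `0:max_interruptions_per_day`.
#' @param interruption_dur_range interruption duration range, min.
#' @param steroid_prob probability of one steroid episode (insulin
#'   resistance x1.5 for 12 h) during the study.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(CHO_mean = 7.5, CHO_sd = 2.0,
                            max_interruptions_per_day = 2,
                            interruption_dur_range = c(60, 180),
                            steroid_prob = 1 / 3) {
  cfg <- as.list(environment())
  if (CHO_sd < 0) stop("CHO_sd must be non-negative")
  if (max_interruptions_per_day < 0 || max_interruptions_per_day > 2)
    stop("max_interruptions_per_day must lie in [0, 2]")
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate a nutrition and resistance scenario
#'
#' Draws a subject's enteral feeding schedule -- a continuous carbohydrate
#' rate with 0--2 interruptions per day of 1--3 h -- and, with probability
#' `steroid_prob`, a 12-h steroid episode during which insulin resistance
#' is increased 1.5-fold.
#'
#' @param seed integer seed.
#' @param duration_h scenario length, hours.
#' @param config a [scenario_config()].
#' @return A list of class `scenario` with fields `CHO_rate` (g/h),
#'   `interruptions` (data frame `start`, `end` in min),
#'   `steroid_start`/`steroid_dur` (min, `NA` if none), `duration_h`.
#' @export
make_scenario <- function(seed = 1, duration_h = 48,
                          config = scenario_config()) {
  set.seed(seed)
  n_min <- duration_h * 60
  cho <- max(0, rnorm(1, config$CHO_mean, config$CHO_sd))
  days <- ceiling(duration_h / 24)
  ints <- list()
  for (d in seq_len(days)) {
    k <- sample(0:config$max_interruptions_per_day, 1)
    if (k > 0) {
      start <- sort(runif(k, (d - 1) * 1440, min(d * 1440, n_min)))
      dur <- runif(k, config$interruption_dur_range[1],
                   config$interruption_dur_range[2])
      ints[[d]] <- data.frame(start = start,
                              end = pmin(start + dur, n_min))
    }
  }
  ints <- if (length(ints)) do.call(rbind, ints) else
    data.frame(start = numeric(0), end = numeric(0))
  steroid <- runif(1) < config$steroid_prob
  structure(list(
    CHO_rate = cho, interruptions = ints,
    steroid_start = if (steroid) runif(1, 0, n_min - 1) else NA_real_,
    steroid_dur = 720, duration_h = duration_h),
    class = "scenario")
}

#' Carbohydrate delivery at a given time
#'
#' @param scenario a [make_scenario()] result.
#' @param t time, min (vectorized).
#' @return Enteral carbohydrate rate(s), g/h (0 during interruptions).
#' @export
scenario_cho_at <- function(scenario, t) {
  out <- rep(scenario$CHO_rate, length(t))
  ints <- scenario$interruptions
  if (nrow(ints)) {
    off <- vapply(t, function(tt) any(tt >= ints$start & tt < ints$end),
                  logical(1))
    out[off] <- 0
  }
  out
}

## Sensitivity modulation including the scenario's steroid episode.
scenario_resistance_at <- function(params, scenario, t) {
  rp <- params$resistance
  rp$steroid_start <- scenario$steroid_start
  rp$steroid_dur <- scenario$steroid_dur
  resistance_at(rp, t)
}

#' Minimization assignment of one subject
#'
#' Taves-style deterministic minimization over the four balancing
#' covariates (APACHE II score, glucose at randomization, BMI, preexisting
#' diabetes). Each covariate is dichotomized (APACHE II > 12, glucose >
#' 10 mM, BMI > 28; diabetes yes/no); the imbalance score of a candidate
#' arm is the sum over covariates of `|countA - countB|` among existing
#' subjects sharing the new subject's category after the hypothetical
#' assignment. The subject joins the arm with the smaller score; exact
#' ties are broken by a fair coin from the current RNG stream.
#'
#' @param new list or data-frame row with fields `apache2`, `G_rand`,
#'   `bmi`, `diabetes`.
#' @param groupA,groupB data frames of the same fields for already
#'   assigned subjects (possibly 0-row).
#' @param cutpoints named list of dichotomization cut-points.
#' @return `"A"` or `"B"`.
#' @export
minimization_assign <- function(new, groupA, groupB,
                                cutpoints = list(apache2 = 12, G_rand = 10,
                                                 bmi = 28)) {
  cat_of <- function(x) c(x$apache2 > cutpoints$apache2,
                          x$G_rand > cutpoints$G_rand,
                          x$bmi > cutpoints$bmi,
                          isTRUE(as.logical(x$diabetes)))
  count_matching <- function(grp, cats) {
    if (is.null(grp) || nrow(grp) == 0) return(rep(0L, 4))
    m <- cbind(grp$apache2 > cutpoints$apache2,
               grp$G_rand > cutpoints$G_rand,
               grp$bmi > cutpoints$bmi,
               as.logical(grp$diabetes))
    vapply(1:4, function(j) sum(m[, j] == cats[j]), integer(1))
  }
  cats <- cat_of(new)
  nA <- count_matching(groupA, cats)
  nB <- count_matching(groupB, cats)
  scoreA <- sum(abs((nA + 1L) - nB))  # imbalance if assigned to A
  scoreB <- sum(abs(nA - (nB + 1L)))
  if (scoreA < scoreB) "A"
  else if (scoreB < scoreA) "B"
  else if (runif(1) < 0.5) "A" else "B"
}

## covariate row used by the trial engine
covariates_of <- function(params) {
  data.frame(apache2 = params$apache2, G_rand = params$G_entry,
             bmi = params$bmi, diabetes = params$diabetes)
}

#' Simulate one trial subject
#'
#' Runs the full event loop for one virtual subject over up to 48 h:
#' physiology at 1-min Runge-Kutta steps, the sensor channel at 1-min
#' steps, reference (arterial) samples every hour, and dosing either by
#' the closed-loop controller every 5 min (arm `"CL"`) or by the hourly
#' sliding-scale nurse cycle (arm `"SS"`). In the closed-loop arm the
#' sensor warm-up hour and any dropout run in reference-fallback mode, and
#' algorithm-requested calibrations are honored at the next minute.
#'
#' @param params a cohort subject from [make_cohort()] (needs `G_entry`
#'   and `basal_insulin`).
#' @param arm `"CL"` (closed-loop) or `"SS"` (sliding scale).
#' @param scenario a [make_scenario()] result.
#' @param seed integer seed for all noise realizations.
#' @param duration_h study duration, hours (<= 48).
#' @param sensor_args list of overrides passed to [sensor_state()].
#' @param control_config a [controller_config()].
#' @param dropout_rate_per_day sensor outage rate (0 disables dropouts).
#' @param escalation enable the sliding-scale escalation rule.
#' @param ref_noise_sd analyzer noise of reference samples, mM.
#' @param sensor_gain_sd SD of the sensor's initial calibration gain.
#' @return An object of class `trial_record`: list with `id`, `arm`,
#'   `reference`, `sensor`, `commands`, `cal_events`, `plasma`,
#'   `nutrition`, `duration_h`.
#' @export
simulate_subject <- function(params, arm = c("CL", "SS"), scenario,
                             seed = 1, duration_h = 48,
                             sensor_args = list(),
                             control_config = controller_config(),
                             dropout_rate_per_day = 1,
                             escalation = FALSE, ref_noise_sd = 0.1,
                             sensor_gain_sd = 0.05) {
  arm <- match.arg(arm)
  if (duration_h <= 0 || duration_h > 48)
    stop("duration_h must lie in (0, 48]")
  set.seed(seed)
  n_min <- as.integer(round(duration_h * 60))

  ## initial physiological state: the subject's calibrated entry state
  ## (steady at the basal insulin rate, reference feeding, modulation
  ## midline), so glucose at randomization equals the sampled G_entry
  calib_CHO <- if (is.null(params$calib_CHO)) 7.5 else params$calib_CHO
  st <- steady_state_glucose(params, params$basal_insulin,
                             CHO = calib_CHO, resistance = 1, full = TRUE)
  sv <- state_vec(st)
  pvec <- param_vec(params)
  vgw <- params$V_G * params$weight

  sensor <- do.call(sensor_state, c(list(
    G_isf = sv[1] / vgw,
    cal_gain = clamp(rnorm(1, 1, sensor_gain_sd), 0.7, 1.3)), sensor_args))
  dropouts <- make_dropout_windows(n_min, rate_per_day = dropout_rate_per_day)

  n_ref <- n_min %/% 60 + 1
  ref_t <- ref_g <- numeric(n_ref)
  sens_t <- sens_g <- rep(NA_real_, n_min + 1)
  plasma_g <- numeric(n_min + 1)
  cmds <- vector("list", if (arm == "CL") n_min %/% 5 else n_ref)
  cal_t <- cal_ref <- cal_dev <- numeric(0)
  notify_log <- numeric(0)

  ## t = 0 events
  plasma_g[1] <- sv[1] / vgw
  ref_hold <- reference_sample(plasma_g[1], sd = ref_noise_sd)
  ref_t[1] <- 0; ref_g[1] <- ref_hold
  i_ref <- 1

  if (arm == "CL") {
    cs <- controller_init(params$weight, ref_hold, control_config)
    step0 <- control_cycle(cs, 0, NA_real_, ref_hold)
    cs <- step0$cs
    cmds[[1]] <- step0$command
    i_cmd <- 1
    ins <- step0$command$insulin_Uh
    dex <- step0$command$dextrose_mLh
  } else {
    ps <- NULL
    nc <- nurse_cycle(ref_hold, ps, escalation)
    ps <- nc$ps
    ins <- nc$rate; dex <- 0
    if (nc$notify) notify_log <- c(notify_log, 0)
    cmds[[1]] <- data.frame(t_min = 0, basis = "sliding-scale",
                            insulin_Uh = ins, dextrose_mLh = 0,
                            internal_G_mM = NA_real_, F_c = NA_real_,
                            b_est = NA_real_, next_cal_due = NA_real_,
                            stringsAsFactors = FALSE)
    i_cmd <- 1
  }

  for (t in seq_len(n_min)) {
    ## advance physiology and sensor over [t-1, t)
    r_t <- scenario_resistance_at(params, scenario, t - 1)
    cho_t <- scenario_cho_at(scenario, t - 1)
    sv <- as.numeric(cpp_advance(sv, pvec, ins, dex, cho_t, r_t, 0, 1, 1L))
    G <- sv[1] / vgw
    plasma_g[t + 1] <- G
    sensor <- sensor_step(sensor, max(G, 0.1), dt = 1)
    avail <- !in_dropout(t, dropouts)
    sread <- sensor_read(sensor, available = avail)
    sens_t[t + 1] <- t; sens_g[t + 1] <- sread

    ## hourly reference sample
    if (t %% 60 == 0) {
      i_ref <- i_ref + 1
      ref_hold <- reference_sample(max(G, 0.1), sd = ref_noise_sd)
      ref_t[i_ref] <- t; ref_g[i_ref] <- ref_hold
      if (arm == "SS") {
        nc <- nurse_cycle(ref_hold, ps, escalation)
        ps <- nc$ps
        ins <- nc$rate
        if (nc$notify) notify_log <- c(notify_log, t)
        i_cmd <- i_cmd + 1
        cmds[[i_cmd]] <- data.frame(t_min = t, basis = "sliding-scale",
                                    insulin_Uh = ins, dextrose_mLh = 0,
                                    internal_G_mM = NA_real_, F_c = NA_real_,
                                    b_est = NA_real_,
                                    next_cal_due = NA_real_,
                                    stringsAsFactors = FALSE)
      }
    }

    if (arm == "CL") {
      ## algorithm-requested calibration, honored at the next minute;
      ## deferred while interstitial glucose changes rapidly, because a
      ## one-point calibration against a lagging signal corrupts the gain
      if (t >= cs$next_cal_due && !is.na(sread) && abs(sensor$roc) <= 0.15) {
        ref_cal <- reference_sample(max(G, 0.1), sd = ref_noise_sd)
        dev <- abs(sread - ref_cal) / ref_cal * 100
        sensor <- sensor_calibrate(sensor, clamp(ref_cal, 1, 40), t = t)
        cs$last_dev <- dev
        cs$last_cal_t <- t
        cs$next_cal_due <- t + schedule_calibration(sread, dev)
        ref_hold <- ref_cal
        cal_t <- c(cal_t, t); cal_ref <- c(cal_ref, ref_cal)
        cal_dev <- c(cal_dev, dev)
      }
      if (t %% 5 == 0 && t < n_min) {
        step <- control_cycle(cs, t, sread, ref_hold)
        cs <- step$cs
        i_cmd <- i_cmd + 1
        cmds[[i_cmd]] <- step$command
        ins <- step$command$insulin_Uh
        dex <- step$command$dextrose_mLh
      }
    }
  }

  commands <- do.call(rbind, cmds[seq_len(i_cmd)])
  structure(list(
    id = NA_integer_, arm = arm,
    reference = data.frame(t = ref_t, G = ref_g),
    sensor = data.frame(t = 0:n_min, G = sens_g,
                        available = !is.na(sens_g)),
    commands = commands,
    cal_events = data.frame(t = cal_t, reference = cal_ref,
                            deviation_pct = cal_dev),
    plasma = data.frame(t = 0:n_min, G = plasma_g),
    nutrition = data.frame(t = 0:n_min,
                           CHO_gh = scenario_cho_at(scenario, 0:n_min)),
    notify_times = notify_log,
    duration_h = duration_h), class = "trial_record")
}

#' Run an in-silico randomized trial
#'
#' Full pipeline: generate a cohort of `2 * n_per_arm` virtual subjects,
#' assign arms by covariate minimization in arrival order (capping each
#' arm at `n_per_arm`), simulate every subject for 48 h under their own
#' nutrition/resistance scenario, and aggregate the endpoint battery.
#'
#' @param n_per_arm subjects per arm (>= 1).
#' @param seed master integer seed; subject seeds are derived from it.
#' @param cohort_cfg a [cohort_config()].
#' @param scenario_cfg a [scenario_config()].
#' @param control_config a [controller_config()].
#' @param duration_h study duration, hours.
#' @param sensor_args overrides for [sensor_state()].
#' @param dropout_rate_per_day sensor outage rate.
#' @return List of class `trial_result` with `records` (list of
#'   `trial_record`), `assignments` (data frame) and `summary` (see
#'   [summarize_trial()]).
#' @export
run_trial <- function(n_per_arm = 12, seed = 1,
                      cohort_cfg = cohort_config(),
                      scenario_cfg = scenario_config(),
                      control_config = controller_config(),
                      duration_h = 48, sensor_args = list(),
                      dropout_rate_per_day = 1) {
  if (n_per_arm < 1) stop("n_per_arm must be >= 1")
  n <- 2L * as.integer(n_per_arm)
  cohort <- make_cohort(n, seed = seed, config = cohort_cfg)
  set.seed(seed + 1L)
  subject_seeds <- sample.int(2^30, n)

  covs <- do.call(rbind, lapply(cohort, covariates_of))
  groupA <- covs[0, ]; groupB <- covs[0, ]
  arm <- character(n)
  set.seed(seed + 2L)
  for (i in seq_len(n)) {
    a <- if (nrow(groupA) >= n_per_arm) "B"
         else if (nrow(groupB) >= n_per_arm) "A"
         else minimization_assign(covs[i, ], groupA, groupB)
    arm[i] <- a
    if (a == "A") groupA <- rbind(groupA, covs[i, ])
    else groupB <- rbind(groupB, covs[i, ])
  }

  records <- vector("list", n)
  for (i in seq_len(n)) {
    scen <- make_scenario(seed = subject_seeds[i] %% 2^30,
                          duration_h = duration_h, config = scenario_cfg)
    rec <- simulate_subject(cohort[[i]],
                            arm = if (arm[i] == "A") "CL" else "SS",
                            scenario = scen, seed = subject_seeds[i],
                            duration_h = duration_h,
                            sensor_args = sensor_args,
                            control_config = control_config,
                            dropout_rate_per_day = dropout_rate_per_day)
    rec$id <- i
    records[[i]] <- rec
  }
  structure(list(records = records,
                 assignments = cbind(covs, arm = arm,
                                     seed = subject_seeds),
                 summary = summarize_trial(records)),
            class = "trial_result")
}
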