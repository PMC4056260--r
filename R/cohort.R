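#' Cohort generator configuration
#'
#' Nominal values and dispersions used by [make_cohort()] to emulate a
#' critically ill cohort with hyperglycemia at study entry. Entry glucose
#' is centered near 10.4 mM, about 46% of subjects carry a diabetes
#' diagnosis, and each subject's overall insulin sensitivity is calibrated
#' so that their steady glucose under their sampled basal insulin rate
#' (0--2 U/h) equals their sampled entry glucose.
#'
#' @param diabetes_prob probability of preexisting diabetes.
#' @param weight_mean,weight_cv lognormal body-weight distribution, kg.
#' @param entry_glucose_mean,entry_glucose_sd Gaussian entry glucose, mM.
#' @param entry_glucose_range truncation bounds for entry glucose, mM.
#' @param basal_insulin_range uniform range of the basal insulin rate at
#'   which the entry glucose is the subject's steady state, U/h.
#' @param param_cv lognormal coefficient of variation applied to the
#'   kinetic constants and sensitivities around their nominal values.
#' @param calib_CHO carbohydrate rate assumed during sensitivity
#'   calibration, g/h.
#' @param bmi_mean,bmi_sd Gaussian BMI, kg/m^2.
#' @param apache_mean,apache_sd Gaussian APACHE II score (rounded, >= 0).
#' @param resist_amp_max maximal relative amplitude of the sinusoidal
#'   insulin-sensitivity modulation.
#' @param resist_period_range period range of the modulation, min.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(diabetes_prob = 0.46, weight_mean = 82,
                          weight_cv = 0.2, entry_glucose_mean = 10.4,
                          entry_glucose_sd = 1.5,
                          entry_glucose_range = c(7, 16),
                          basal_insulin_range = c(1, 2),
                          param_cv = 0.15, calib_CHO = 7.5,
                          bmi_mean = 28, bmi_sd = 3,
                          apache_mean = 12, apache_sd = 4,
                          resist_amp_max = 0.4,
                          resist_period_range = c(240, 720)) {
  cfg <- as.list(environment())
  if (diabetes_prob < 0 || diabetes_prob > 1)
    stop("diabetes_prob must lie in [0, 1]")
  if (param_cv < 0 || param_cv > 1) stop("param_cv must lie in [0, 1]")
  if (basal_insulin_range[1] < 0 || basal_insulin_range[2] > 2 ||
      diff(basal_insulin_range) < 0)
    stop("basal_insulin_range must be an increasing range within [0, 2]")
  if (resist_amp_max < 0 || resist_amp_max > 0.4)
    stop("resist_amp_max must lie in [0, 0.4]")
  class(cfg) <- "cohort_config"
  cfg
}

## lognormal draw with given mean and CV
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## Scale S_IT/S_ID/S_IE jointly by m so that the steady glucose at
## (basal_u, CHO) equals G0; monotone bisection in m (glucose is strictly
## decreasing in m; loss of equilibrium treated as glucose 0).
solve_sensitivity_scale <- function(params, G0, basal_u, CHO,
                                    interval = c(0.01, 20)) {
  g_at <- function(m) {
    p <- params
    p$S_IT <- p$S_IT * m; p$S_ID <- p$S_ID * m; p$S_IE <- p$S_IE * m
    tryCatch(steady_state_glucose(p, basal_u, CHO = CHO),
             error = function(e) 0)
  }
  lo <- interval[1]; hi <- interval[2]
  if (g_at(lo) < G0)
    stop("entry glucose not attainable: subject too resistant to calibrate")
  if (g_at(hi) > G0)
    stop("entry glucose not attainable: subject too sensitive to calibrate")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (g_at(mid) >= G0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a virtual cohort
#'
#' Draws `n` virtual subjects. Kinetic constants and sensitivities are
#' sampled log-normally around the nominal values of [patient_params()];
#' each subject's three insulin sensitivities are then jointly rescaled so
#' that the subject's steady glucose under their basal insulin rate
#' (uniform on `basal_insulin_range`) equals their sampled entry glucose.
#' A smooth sinusoidal insulin-sensitivity modulation (period 4--12 h,
#' amplitude up to +/-40%) provides intra-patient variability.
#'
#' @param n number of subjects (>= 1).
#' @param seed integer seed; the cohort is a pure function of
#'   `(n, seed, config)`.
#' @param config a [cohort_config()].
#' @return List of [patient_params()] objects; each carries additional
#'   fields `G_entry` (mM) and `basal_insulin` (U/h).
#' @export
make_cohort <- function(n, seed = 1, config = cohort_config()) {
  if (n < 1) stop("n must be >= 1")
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  set.seed(seed)
  out <- vector("list", n)
  nom <- patient_params()
  for (i in seq_len(n)) {
    repeat {
      weight <- clamp(rlnorm_cv(1, config$weight_mean, config$weight_cv),
                      40, 200)
      G0 <- clamp(rnorm(1, config$entry_glucose_mean, config$entry_glucose_sd),
                  config$entry_glucose_range[1], config$entry_glucose_range[2])
      u0 <- runif(1, config$basal_insulin_range[1],
                  config$basal_insulin_range[2])
      cv <- config$param_cv
      p <- try(patient_params(
        weight = weight,
        V_G = rlnorm_cv(1, nom$V_G, cv), k12 = rlnorm_cv(1, nom$k12, cv),
        F01 = rlnorm_cv(1, nom$F01, cv), EGP0 = rlnorm_cv(1, nom$EGP0, cv),
        V_I = rlnorm_cv(1, nom$V_I, cv), k_e = rlnorm_cv(1, nom$k_e, cv),
        k_a1 = rlnorm_cv(1, nom$k_a1, cv), k_a2 = rlnorm_cv(1, nom$k_a2, cv),
        k_a3 = rlnorm_cv(1, nom$k_a3, cv),
        S_IT = rlnorm_cv(1, nom$S_IT, cv), S_ID = rlnorm_cv(1, nom$S_ID, cv),
        S_IE = rlnorm_cv(1, nom$S_IE, cv),
        resistance = resistance_profile(
          amplitude = runif(1, 0, config$resist_amp_max),
          period_min = runif(1, config$resist_period_range[1],
                             config$resist_period_range[2]),
          phase = runif(1, 0, 2 * pi)),
        diabetes = rbinom(1, 1, config$diabetes_prob) == 1,
        apache2 = max(0, round(rnorm(1, config$apache_mean,
                                     config$apache_sd))),
        bmi = max(15, rnorm(1, config$bmi_mean, config$bmi_sd))),
        silent = TRUE)
      if (inherits(p, "try-error")) next
      m <- try(solve_sensitivity_scale(p, G0, u0, config$calib_CHO),
               silent = TRUE)
      if (inherits(m, "try-error")) next
      p$S_IT <- p$S_IT * m; p$S_ID <- p$S_ID * m; p$S_IE <- p$S_IE * m
      p$G_entry <- G0
      p$basal_insulin <- u0
      p$calib_CHO <- config$calib_CHO
      out[[i]] <- p
      break
    }
  }
  out
}
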