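#' Virtual-patient parameters
#'
#' Construct the parameter set of a virtual critically ill adult. The
#' physiology is a two-compartment model of glucose kinetics with three
#' remote insulin actions (on glucose transport, disposal, and endogenous
#' glucose production) and a first-order gut delay for enteral
#' carbohydrate. Defaults are nominal adult values for this model family;
#' cohort-level variability is added by [make_cohort()].
#'
#' @param weight body weight, kg (40--200).
#' @param V_G glucose distribution volume, L/kg.
#' @param k12 transfer rate between accessible and non-accessible glucose
#'   compartments, 1/min.
#' @param F01 non-insulin-dependent glucose flux, mmol/kg/min.
#' @param EGP0 endogenous glucose production extrapolated to zero insulin
#'   action, mmol/kg/min.
#' @param V_I insulin distribution volume, L/kg.
#' @param k_e plasma insulin elimination rate, 1/min.
#' @param k_a1,k_a2,k_a3 activation rates of the three remote insulin
#'   actions, 1/min.
#' @param S_IT,S_ID,S_IE insulin sensitivities of transport, disposal and
#'   EGP suppression (steady-state action per mU/L).
#' @param gut_tau time constant of the enteral carbohydrate gut delay, min.
#' @param resistance list describing the smooth multiplicative
#'   insulin-sensitivity modulation, see [resistance_profile()].
#' @param diabetes logical, preexisting diabetes.
#' @param apache2 APACHE II severity score (randomization covariate only).
#' @param bmi body mass index, kg/m^2 (randomization covariate only).
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(weight = 80, V_G = 0.16, k12 = 0.066,
                           F01 = 0.0097, EGP0 = 0.0161, V_I = 0.12,
                           k_e = 0.138, k_a1 = 0.006, k_a2 = 0.06,
                           k_a3 = 0.03, S_IT = 51.2e-4, S_ID = 8.2e-4,
                           S_IE = 520e-4, gut_tau = 40,
                           resistance = resistance_profile(),
                           diabetes = FALSE, apache2 = 12, bmi = 28) {
  p <- list(weight = weight, V_G = V_G, k12 = k12, F01 = F01, EGP0 = EGP0,
            V_I = V_I, k_e = k_e, k_a1 = k_a1, k_a2 = k_a2, k_a3 = k_a3,
            S_IT = S_IT, S_ID = S_ID, S_IE = S_IE, gut_tau = gut_tau,
            resistance = resistance, diabetes = isTRUE(diabetes),
            apache2 = apache2, bmi = bmi)
  rates <- c(V_G, k12, F01, EGP0, V_I, k_e, k_a1, k_a2, k_a3,
             S_IT, S_ID, S_IE, gut_tau)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants, sensitivities and volumes must be positive")
  if (!is.finite(weight) || weight < 40 || weight > 200)
    stop("weight must lie in [40, 200] kg")
  if (apache2 < 0) stop("apache2 must be non-negative")
  class(p) <- "patient_params"
  p
}

#' Smooth time-varying insulin-resistance modulation
#'
#' A sinusoidal multiplicative modulation of insulin sensitivity around 1,
#' optionally with a steroid episode during which sensitivity is divided by
#' `steroid_factor`. The evaluated profile is clamped to \[0.2, 3\].
#'
#' @param amplitude relative amplitude of the sinusoid (0 to 0.4).
#' @param period_min period, minutes (240--720 typical).
#' @param phase phase, radians.
#' @param steroid_start start of a steroid episode, min (`NA` for none).
#' @param steroid_dur duration of the episode, min.
#' @param steroid_factor fold-increase in insulin resistance during the
#'   episode (sensitivity is multiplied by `1/steroid_factor`).
#' @return A list of class `resistance_profile`.
#' @export
resistance_profile <- function(amplitude = 0, period_min = 480, phase = 0,
                               steroid_start = NA_real_, steroid_dur = 720,
                               steroid_factor = 1.5) {
  if (amplitude < 0 || amplitude > 0.4)
    stop("amplitude must lie in [0, 0.4]")
  if (period_min <= 0) stop("period_min must be positive")
  structure(list(amplitude = amplitude, period_min = period_min,
                 phase = phase, steroid_start = steroid_start,
                 steroid_dur = steroid_dur, steroid_factor = steroid_factor),
            class = "resistance_profile")
}

#' Evaluate the insulin-sensitivity modulation at time t
#'
#' @param rp a [resistance_profile()].
#' @param t time since trial start, min (vectorized).
#' @return Multiplicative sensitivity factor(s), clamped to \[0.2, 3\].
#' @export
resistance_at <- function(rp, t) {
  r <- 1 + rp$amplitude * sin(2 * pi * t / rp$period_min + rp$phase)
  if (!is.na(rp$steroid_start)) {
    on <- t >= rp$steroid_start & t < rp$steroid_start + rp$steroid_dur
    r[on] <- r[on] / rp$steroid_factor
  }
  clamp(r, 0.2, 3)
}

#' Virtual-patient state
#'
#' @param Q1,Q2 glucose masses in the accessible / non-accessible
#'   compartment, mmol.
#' @param I plasma insulin, mU/L.
#' @param x1,x2,x3 remote insulin actions.
#' @param Qg gut carbohydrate, g.
#' @param t minutes since trial start.
#' @return An object of class `patient_state`.
#' @export
patient_state <- function(Q1, Q2 = 0, I = 0, x1 = 0, x2 = 0, x3 = 0,
                          Qg = 0, t = 0) {
  v <- c(Q1 = Q1, Q2 = Q2, I = I, x1 = x1, x2 = x2, x3 = x3, Qg = Qg)
  if (any(!is.finite(v))) stop("degenerate state: non-finite component")
  if (any(v < 0)) stop("state components must be non-negative")
  structure(list(Q1 = Q1, Q2 = Q2, I = I, x1 = x1, x2 = x2, x3 = x3,
                 Qg = Qg, t = t), class = "patient_state")
}

#' Exogenous inputs to the virtual patient
#'
#' @param insulin_rate intravenous insulin, U/h (0--50; 1 U/mL solution).
#' @param dextrose_rate 20% dextrose, mL/h (0--200; 0.2 g glucose per mL).
#' @param enteral_CHO enteral carbohydrate, g/h.
#' @return An object of class `exogenous_input`.
#' @export
exogenous_input <- function(insulin_rate = 0, dextrose_rate = 0,
                            enteral_CHO = 0) {
  if (insulin_rate < 0 || insulin_rate > 50)
    stop("insulin_rate must lie in [0, 50] U/h")
  if (dextrose_rate < 0 || dextrose_rate > 200)
    stop("dextrose_rate must lie in [0, 200] mL/h")
  if (enteral_CHO < 0) stop("enteral_CHO must be non-negative")
  structure(list(insulin_rate = insulin_rate, dextrose_rate = dextrose_rate,
                 enteral_CHO = enteral_CHO), class = "exogenous_input")
}

## Parameter vector handed to the compiled kernels.
param_vec <- function(params) {
  c(params$weight, params$V_G, params$k12, params$F01, params$EGP0,
    params$V_I, params$k_e, params$k_a1, params$k_a2, params$k_a3,
    params$S_IT, params$S_ID, params$S_IE, params$gut_tau)
}

state_vec <- function(state) {
  c(state$Q1, state$Q2, state$I, state$x1, state$x2, state$x3, state$Qg)
}

vec_state <- function(v, t) {
  patient_state(Q1 = v[1], Q2 = v[2], I = v[3], x1 = v[4], x2 = v[5],
                x3 = v[6], Qg = v[7], t = t)
}

#' Plasma glucose of a state
#'
#' @param state a [patient_state()].
#' @param params the matching [patient_params()].
#' @return Plasma glucose, mM (`Q1 / (V_G * weight)`).
#' @export
plasma_glucose <- function(state, params) {
  state$Q1 / (params$V_G * params$weight)
}

#' Model derivatives
#'
#' Time derivative of every state component under the declared compartment
#' model:
#' \deqn{dQ_1/dt = -F_{01} w \min(1, G/4.5) - x_1 Q_1 + k_{12} Q_2 +
#'       EGP_0 w \max(0, 1 - x_3) + R_a + F_c}
#' \deqn{dQ_2/dt = x_1 Q_1 - (k_{12} + x_2) Q_2}
#' \deqn{dI/dt = u/(V_I w) - k_e I, \quad
#'       dx_i/dt = -k_{ai} x_i + k_{ai} S_i \, r(t) \, I}
#' where glucose appearance \eqn{R_a} combines intravenous dextrose
#' (converted at 0.2 g/mL and 5.551 mmol/g) and the outflow of a
#' first-order gut compartment fed by enteral carbohydrate.
#'
#' @param state a [patient_state()].
#' @param params a [patient_params()].
#' @param input an [exogenous_input()].
#' @param resistance multiplicative sensitivity factor at the current time
#'   (default: evaluated from `params$resistance`).
#' @param Fc additive glucose flux, mmol/min (controller-internal use).
#' @return Named numeric vector of derivatives per minute.
#' @export
derivatives <- function(state, params, input = exogenous_input(),
                        resistance = NULL, Fc = 0) {
  s <- state_vec(state)
  if (any(!is.finite(s))) stop("degenerate state: non-finite component")
  if (is.null(resistance))
    resistance <- resistance_at(params$resistance, state$t)
  w <- params$weight
  ra_gut <- MMOL_PER_G * state$Qg / params$gut_tau
  ra_dex <- input$dextrose_rate * 0.2 * MMOL_PER_G / 60
  egp <- params$EGP0 * w * max(0, 1 - state$x3)
  u_mU_min <- input$insulin_rate * 1000 / 60
  G <- state$Q1 / (params$V_G * w)
  f01c <- params$F01 * w * min(1, G / 4.5)
  c(Q1 = -f01c - state$x1 * state$Q1 + params$k12 * state$Q2 +
        egp + ra_gut + ra_dex + Fc,
    Q2 = state$x1 * state$Q1 - (params$k12 + state$x2) * state$Q2,
    I  = u_mU_min / (params$V_I * w) - params$k_e * state$I,
    x1 = -params$k_a1 * state$x1 +
         params$k_a1 * params$S_IT * resistance * state$I,
    x2 = -params$k_a2 * state$x2 +
         params$k_a2 * params$S_ID * resistance * state$I,
    x3 = -params$k_a3 * state$x3 +
         params$k_a3 * params$S_IE * resistance * state$I,
    Qg = input$enteral_CHO / 60 - state$Qg / params$gut_tau)
}

#' Advance the virtual patient by one fixed step
#'
#' Classical 4th-order Runge-Kutta with constant inputs over the step.
#' Components that undershoot zero are clipped to zero; the number of
#' clipped components is attached as attribute `"n_clipped"`.
#'
#' @inheritParams derivatives
#' @param dt step size, min, in (0, 5\]. Default 1.
#' @param n number of steps of size `dt` to take.
#' @return The advanced [patient_state()].
#' @export
patient_step <- function(state, params, input = exogenous_input(), dt = 1,
                         n = 1, resistance = NULL, Fc = 0) {
  if (dt <= 0 || dt > 5) stop("dt must lie in (0, 5] minutes")
  if (is.null(resistance))
    resistance <- resistance_at(params$resistance, state$t)
  v <- cpp_advance(state_vec(state), param_vec(params),
                   input$insulin_rate, input$dextrose_rate,
                   input$enteral_CHO, resistance, Fc, dt, as.integer(n))
  out <- vec_state(v, state$t + dt * n)
  attr(out, "n_clipped") <- attr(v, "n_clipped")
  out
}

#' Closed-form steady-state glucose
#'
#' Equilibrium plasma glucose of the compartment model under constant
#' insulin and carbohydrate delivery, solved analytically: insulin and the
#' remote actions equilibrate at \eqn{I^* = u/(V_I w k_e)} and
#' \eqn{x_i^* = S_i r I^*}; the glucose balance is then linear in
#' \eqn{Q_1} on each branch of the saturating non-insulin-dependent
#' uptake. On the plateau branch (\eqn{G \ge 4.5} mM)
#' \deqn{Q_1^* = \frac{(EGP_0 w \max(0, 1 - x_3^*) + R_a - F_{01} w)
#'       (k_{12} + x_2^*)}{x_1^* x_2^*},}
#' otherwise the proportional-uptake branch applies. Errors when no
#' positive equilibrium exists (zero insulin effect with net positive
#' glucose flux, or zero glucose appearance).
#'
#' @param params a [patient_params()].
#' @param insulin_rate constant insulin, U/h.
#' @param CHO constant enteral carbohydrate, g/h.
#' @param dextrose_rate constant 20% dextrose, mL/h.
#' @param resistance constant sensitivity factor (default 1: the profile
#'   midline).
#' @param full if `TRUE`, return the full equilibrium [patient_state()]
#'   instead of the glucose value.
#' @return Steady-state plasma glucose, mM, or a `patient_state`.
#' @export
steady_state_glucose <- function(params, insulin_rate, CHO = 0,
                                 dextrose_rate = 0, resistance = 1,
                                 full = FALSE) {
  if (insulin_rate < 0) stop("insulin_rate must be non-negative")
  w <- params$weight
  Istar <- insulin_rate * 1000 / 60 / (params$V_I * w * params$k_e)
  x1 <- params$S_IT * resistance * Istar
  x2 <- params$S_ID * resistance * Istar
  x3 <- params$S_IE * resistance * Istar
  Ra <- CHO * MMOL_PER_G / 60 + dextrose_rate * 0.2 * MMOL_PER_G / 60
  vgw <- params$V_G * w
  E <- params$EGP0 * w * max(0, 1 - x3)
  num <- E + Ra - params$F01 * w
  ## removal-rate coefficient of the insulin-dependent pathway (per min)
  cc <- if (x1 > 0 && x2 > 0) x1 * x2 / (params$k12 + x2) else 0
  if (cc > 0 && num > 0) {
    Q1 <- num / cc          # branch with uptake at its plateau (G >= 4.5)
    if (Q1 / vgw < 4.5) Q1 <- NA_real_
  } else if (cc == 0 && num > 0) {
    stop("no finite equilibrium: insulin has no effect and net flux is positive")
  } else Q1 <- NA_real_
  if (is.na(Q1)) {
    ## proportional-uptake branch (G < 4.5): uptake F01*w*G/4.5
    if (E + Ra <= 0) stop("no positive equilibrium")
    Q1 <- (E + Ra) / (cc + params$F01 * w / (4.5 * vgw))
    if (Q1 / vgw >= 4.5) stop("no positive equilibrium")
  }
  if (!full) return(Q1 / vgw)
  Q2 <- x1 * Q1 / (params$k12 + x2)
  patient_state(Q1 = Q1, Q2 = Q2, I = Istar, x1 = x1, x2 = x2, x3 = x3,
                Qg = CHO * params$gut_tau / 60, t = 0)
}

#' Constant insulin rate holding a given steady glucose
#'
#' Inverts [steady_state_glucose()] by monotone bisection: steady glucose
#' is strictly decreasing in the insulin rate wherever an equilibrium
#' exists, and rates beyond the loss of a positive equilibrium are treated
#' as driving glucose to zero.
#'
#' @inheritParams steady_state_glucose
#' @param target_G desired steady plasma glucose, mM.
#' @param interval search interval for the rate, U/h.
#' @return Insulin rate, U/h.
#' @export
insulin_for_glucose <- function(params, target_G, CHO = 0, resistance = 1,
                                interval = c(1e-4, 50)) {
  f <- function(u) {
    g <- tryCatch(steady_state_glucose(params, u, CHO = CHO,
                                       resistance = resistance),
                  error = function(e) 0)
    g - target_G
  }
  lo <- interval[1]; hi <- interval[2]
  if (f(lo) < 0)
    stop("target_G not attainable: steady glucose below target even at ",
         lo, " U/h")
  if (f(hi) > 0)
    stop("target_G not attainable within the search interval")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
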