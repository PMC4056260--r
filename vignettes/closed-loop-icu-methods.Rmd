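---
title: "Methods: simulating fully automated closed-loop glucose control in critical illness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating closed-loop glucose control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucoloop)
```

## What this package simulates

`glucoloop` is an in-silico test bed for automated glucose control in
critically ill adults. It pits two dosing policies against the same
virtual patients over 48 hours:

* a **closed-loop arm**: a model-predictive controller that, every
  5 minutes, turns subcutaneous continuous glucose monitor (CGM) readings
  into an intravenous insulin rate or, at low glucose, a 20% dextrose
  rate, with no nurse input; and
* a **sliding-scale arm**: the conventional paper protocol in which a
  nurse reads the hourly arterial glucose and sets the insulin rate from
  a fixed lookup table.

Both arms are driven by hourly arterial reference samples for outcome
assessment, and the trial engine assigns subjects to arms by covariate
minimization. Every protocol constant of the system -- the 50 U/h insulin
and 200 mL/h dextrose caps, the suspend rule 1.2 mM below target, the
5-min control cycle, the 1-h sensor warm-up, the 15-min blood-to-sensor
lag, the 30-min low-glucose calibration interval -- is an executable,
testable piece of code.

## The virtual patient

### Model structure

The physiology is the well-known two-compartment model of glucose
kinetics with three remote insulin actions. States are the accessible and
non-accessible glucose masses $Q_1, Q_2$ (mmol), plasma insulin $I$
(mU/L), insulin actions $x_1, x_2, x_3$ (transport, disposal, suppression
of endogenous glucose production), and a gut carbohydrate store $Q_g$
(g):

$$\frac{dQ_1}{dt} = -F_{01}w\,\min(1, G/4.5) - x_1 Q_1 + k_{12} Q_2 +
  EGP_0\,w\,\max(0, 1 - x_3) + R_a$$
$$\frac{dQ_2}{dt} = x_1 Q_1 - (k_{12} + x_2) Q_2, \qquad
  \frac{dI}{dt} = \frac{u}{V_I w} - k_e I$$
$$\frac{dx_i}{dt} = -k_{ai} x_i + k_{ai} S_i\, r(t)\, I, \qquad
  \frac{dQ_g}{dt} = \frac{\text{CHO}}{60} - \frac{Q_g}{\tau_g}$$

with plasma glucose $G = Q_1/(V_G w)$ and glucose appearance $R_a$
combining the gut outflow ($5.551\ \mathrm{mmol/g} \cdot Q_g/\tau_g$) and
intravenous 20% dextrose ($0.2$ g/mL). Insulin is infused as a 1 U/mL
solution, so commanded U/h convert directly to mU/min.

Two structural choices deserve comment:

* **Saturating non-insulin-dependent uptake.** Below 4.5 mM the
  non-insulin-dependent flux is proportional to glucose,
  $F_{01}w \cdot G/4.5$, the standard saturating form in this model
  family. This matters: with a constant $-F_{01}w$ drain, a feeding
  interruption would drive glucose monotonically to zero no matter what
  any controller does, which is neither physiological nor a fair test of
  hypoglycemia avoidance. The steady state remains available in closed
  form because the glucose balance is linear in $Q_1$ on each branch of
  the saturation (`steady_state_glucose()`).
* **First-order gut delay** ($\tau_g = 40$ min) between the enteral
  carbohydrate rate and glucose appearance; no more elaborate meal model
  is attempted, since feeding in this setting is a continuous infusion
  with occasional interruptions rather than discrete meals.

Nominal parameter values (`patient_params()`) are standard adult values
for this model family, e.g. $V_G = 0.16$ L/kg, $k_{12} = 0.066$/min,
$F_{01} = 0.0097$ and $EGP_0 = 0.0161$ mmol/kg/min, $k_e = 0.138$/min.
They are implementation-chosen constants, exposed as arguments.

### Cohort generation

`make_cohort()` emulates a critically ill cohort with hyperglycemia at
study entry: entry glucose is Gaussian around 10.4 mM (truncated to
7--16), 46% of subjects carry a diabetes diagnosis, body weight is
lognormal around 82 kg, and APACHE II and BMI are sampled as
randomization covariates only. Kinetic constants are drawn log-normally
(CV 0.15) around the nominal values.

The key calibration step: each subject's three insulin sensitivities are
jointly rescaled so that the subject's steady glucose *at their own basal
insulin rate* (uniform 1--2 U/h, emulating patients already on insulin
infusions at rates around 1.5--2.5 U/h) *equals their sampled entry
glucose* under reference feeding (7.5 g/h carbohydrate). This anchors the
cohort to the two quantities such trials actually report -- entry glucose
and insulin infusion rates -- rather than to unobservable sensitivity
parameters, and it guarantees that baseline steady glucose falls in
8--14 mM for well over 90% of subjects.

Intra-patient variability is a smooth sinusoidal modulation of insulin
sensitivity (period 4--12 h, amplitude up to ±40%, clamped to
[0.2, 3]), plus scenario-level events: feeding interruptions (0--2 per
day, 1--3 h) and, in a third of subjects, a 12-h steroid episode that
multiplies insulin resistance by 1.5.

What the generator does **not** emulate: circadian hormones, sepsis
dynamics, renal glucose excretion, measurement-site effects,
drug--glucose interactions beyond the generic resistance profile, or
pediatric physiology. Passing tests therefore demonstrate internal
consistency of the control system under realistic-magnitude disturbances,
not clinical performance on real patients.

## The CGM model

The sensor channel (`sensor_state()`) is a first-order blood-to-
interstitial lag with time constant 15 min, a multiplicative calibration
gain with slow linear drift (0.005/h), additive Gaussian reading noise,
a 1-hour warm-up with no readings, Poisson dropouts (one per day on
average, lognormal ~10-min durations), and a 1.1 mM display floor.
One-point calibration resets the gain so the post-calibration reading
equals the arterial reference; calibration is deferred while the
interstitial signal changes faster than 0.15 mM/min, because calibrating
a lagging signal during rapid flux corrupts the gain -- real CGM
calibration schedules defer for the same reason.

The reading noise default (0.45 mM) was set by `tune_sensor_noise()`,
which bisects on the noise SD until the simulated 48-h median relative
absolute deviation against hourly references hits a 7% target; the
bisection uses common random numbers so the simulated MARD is monotone in
the noise SD. Only summary accuracy is emulated; the real sensor's noise
spectrum is not.

## The closed-loop controller

Every 5 minutes the controller (`control_cycle()`):

1. takes the current sensor reading, or falls back to the latest hourly
   reference (zero-order hold) during warm-up or dropouts;
2. assimilates the observation into an internal copy of the compartment
   model (nominal parameters at the patient's weight);
3. either doses 20% dextrose from a 40-min zero-insulin prediction, or
   optimizes the insulin rate over a 90-min prediction horizon;
4. applies the safety rules and schedules the next reference request
   (every 1--6 h depending on sensor-reference deviation; every 30 min
   below 3.5 mM).

### The two adaptive parameters

The controller individualizes itself through exactly two quantities:

* $F_c$, a rapidly changing additive glucose flux (mmol/min) correcting
  model-prediction errors. It is a leaky integrator of the innovation
  $e = G_{obs} - \hat G$ with a 30-min time constant; its gain is chosen
  so a sustained 1 mM innovation asymptotes to the flux that would close
  the corresponding mass error in one time constant.
* $b_{est}$, a slowly changing estimate of the insulin rate maintaining
  euglycemia (U/h), accumulated as $k_b \int e\,dt$ with
  $k_b = 5\times10^{-3}$ U/h per mM·min (effective adaptation over a few
  hours) and clamped to [0, 50].

$b_{est}$ enters the model multiplicatively: the internal sensitivities
are scaled by $m = u_{nom}/b_{est}$, where $u_{nom}$ is the rate at which
the nominal model holds the 7.0 mM setpoint. By construction the internal
model is then in steady state at the setpoint exactly when $u = b_{est}$,
which gives the estimate its literal meaning and makes its fixed point
the patient's true steady requirement: the closed loop is in equilibrium
only when glucose sits at target, the model matches the observations, and
the commanded rate equals both $b_{est}$ and the patient's requirement.
This fixed-point property is what the parameter-recovery test checks
(±20% after 24 h of constant conditions).

Two supporting estimator choices:

* an **observer correction** moves the internal glucose mass a fraction
  (0.6) of each innovation toward the observation, so predictions start
  from the assimilated level -- with parameter adaptation alone the model
  tracked too loosely and the loop limit-cycled;
* the internal model carries a fixed **background appearance prior**
  (7.5 g/h carbohydrate equivalent). The algorithm receives *no*
  information about actual nutrition; the prior only prevents the
  sensitivity scaling from attributing feeding-driven insulin demand to
  insulin resistance, which would make the internal dose-response several
  times shallower than any patient's and cause systematic overdosing.
  $F_c$ absorbs the actual feeding variation.

### The insulin optimizer

The rate minimizes
$J(u) = \sum_k (\hat G_k(u) - G_{target})^2 + \lambda_u (u - u_{prev})^2$
over the grid $u = 0, 0.05, \ldots, 50$ U/h, predictions on a 5-min grid
over 90 min. The default search scans a 0.5 U/h coarse grid and refines
at 0.05 U/h around the optimum; tests verify against exhaustive and
10×-finer brute force. $\lambda_u = 5$, i.e. a 1 U/h move costs as much
as a sustained ~0.53 mM offset over the horizon; smaller values
(e.g. equivalent to a 0.3 mM offset) were insufficient to damp the loop
against the steep dose-response of calibrated subjects.

### Safety rules

All dosing passes through, in order: dextrose/insulin mutual exclusion
(dextrose is dosed proportionally, 200 mL/h per mM of predicted shortfall
below 4.5 mM, capped at 200 mL/h, and forces insulin to zero); the
suspend rule (insulin 0 whenever observed glucose is at or below
target − 1.2 mM -- the boundary counts as suspended); a fallback cap
(while dosing on reference values the command cannot exceed
1.25 × $b_{est}$ -- without continuous feedback the controller stays near
its basal estimate); a fall-rate guard (no escalation above
max($u_{prev}$, $b_{est}$) when observed glucose falls faster than
0.06 mM/min, cap $b_{est}/2$ beyond 0.12 mM/min); a predictive
feasibility constraint (the chosen rate's own 90-min prediction must stay
above the suspend level, else the rate backs off by bisection -- valid
because predictions are monotone in $u$); an aggressiveness cap
(max(2, 3 × $b_{est}$) U/h); and the hard 50 U/h / 200 mL/h clamps. The
low-glucose rules (suspend and rescue) act on the observation projected
forward by the 15-min sensor lag when glucose is falling, since the
controller knows blood leads the sensor on the way down.

## The comparator protocol

`lookup_rate()` implements the printed intravenous sliding scale: bands
of 0.1-mM-rounded blood glucose map to fixed rates (e.g. 7.1--8.5 mM →
1.5 U/h, >20 mM → 6 U/h, <4 mM → nil), with physician-notification
flags. Rounding to one decimal before lookup is what makes the printed
bands a partition. The hourly nurse cycle holds the rate between
measurements; an optional deterministic escalation rule (+1 row after two
consecutive readings above 12 mM) is off by default because the real
behavior ("physician-prescribed alteration") is unspecifiable. The first
band boundary is read as "> 20.0".

## Trial engine and statistics

`minimization_assign()` implements Taves-style deterministic minimization
over APACHE II (≤/> 12), randomization glucose (≤/> 10 mM), BMI
(≤/> 28) and diabetes, with fair-coin ties; cut-points sit near the
cohort medians and are exposed as arguments. `run_trial()` caps each arm
at the target size so a 12 + 12 trial has exactly 12 subjects per arm.
The whole trial is a pure function of its seed.

The endpoint battery mirrors the standard reporting shape: time in the
primary 6.0--8.0 mM band and wider/outer bands from the hourly reference
trace; mean and SD of reference glucose; counts of hyperglycemic
(≥15, ≥17 mM) and hypoglycemic (<4 mM) episodes, an episode being a
maximal run of consecutive out-of-range samples; insulin and dextrose
totals from the zero-order-hold command log; sensor MAD/MARD/%-within-20%
on nearest-in-5-min pairs; calibration counts per study day; and sensor
unavailability. Time in range interpolates the hourly references
piecewise-linearly with analytic band crossings (a sample-counting mode
exists for sensitivity analysis, since the original outcome software's
convention is unpublished). Between-arm comparisons use a tie-aware exact
Mann--Whitney U test (full enumeration up to group size 9, tie- and
continuity-corrected normal approximation beyond) for the skewed
endpoints and a pooled-variance t test for the per-subject glucose SD,
presented as median (IQR) and mean (SD) respectively.

## Numerical choices

* Fixed-step classical Runge--Kutta at 1-min steps for physiology and
  5-min steps for controller predictions (the system's fastest time
  constant, $k_e = 0.138$/min, keeps RK4 comfortably accurate at both);
  verified against a 0.001-min Euler oracle to 0.01 mM.
* Components that undershoot zero are clipped to zero with a count
  attribute, rather than invoking stiff-solver machinery.
* Steady states and their insulin inverses are solved by monotone
  bisection (60 iterations), treating loss of a positive equilibrium as
  glucose zero so the bracketing stays valid.
* The exact Mann--Whitney p sums both tails of the permutation
  distribution of U, which is symmetric about $n_1 n_2 / 2$ even under
  ties; p is capped at 1.

## Problem sizes

The shipped tests and the acceptance script use: 48-h subjects at 1-min
physiology steps (2880 steps, 576 control cycles); a 12 + 12 trial for
the directional and safety endpoints; 10 subjects × 24 h for parameter
recovery; 1000 subjects for cohort distribution checks; 100 randomized
controller states for the optimizer oracle; and 6-h trajectories for the
integrator oracle. These sizes were chosen so the full suite exercises
every code path at desk scale.

## Known limitations

The virtual cohort's dose-response is steeper than real ICU populations
report, a structural property of the multiplicative insulin-action model;
the calibration to observed entry glucose and basal rates anchors the
operating point but not the curvature. The comparator arm omits ad-hoc
physician boluses. Clinical central values from any real trial are
properties of 24 specific patients and are not reproduction targets here;
the package's claims are directional (closed-loop spends more time in
band, less above 10 mM, without reference hypoglycemia) and structural
(every protocol constant behaves as printed).
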