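test_that("derivatives have the declared structure at rest", {
  p <- patient_params()
  ## glucose above the uptake saturation knee, no insulin, no actions
  st <- patient_state(Q1 = 7 * p$V_G * p$weight)
  d0 <- derivatives(st, p, exogenous_input())
  expect_equal(unname(d0["Q1"]), -p$F01 * p$weight + p$EGP0 * p$weight)
  expect_equal(unname(d0["Q2"]), 0)
  expect_equal(unname(d0["I"]), 0)

  ## 200 mL/h of 20% dextrose appears as 40 g/h = 3.70 mmol/min
  d_dex <- derivatives(st, p, exogenous_input(dextrose_rate = 200))
  expect_equal(unname(d_dex["Q1"] - d0["Q1"]), 200 * 0.2 * 5.551 / 60,
               tolerance = 1e-12)

  ## enteral carbohydrate feeds the gut compartment, not Q1 directly
  d_cho <- derivatives(st, p, exogenous_input(enteral_CHO = 12))
  expect_equal(unname(d_cho["Qg"]), 12 / 60)
  expect_equal(unname(d_cho["Q1"]), unname(d0["Q1"]))

  ## non-finite state is rejected
  st_bad <- st
  st_bad$Q1 <- NaN
  expect_error(derivatives(st_bad, p, exogenous_input()), "degenerate")
})

test_that("compiled and R derivatives agree", {
  p <- nominal_test_patient()
  set.seed(42)
  for (i in 1:20) {
    sv <- c(runif(1, 10, 300), runif(1, 0, 100), runif(1, 0, 60),
            runif(3, 0, 0.5), runif(1, 0, 10))
    st <- glucoloop:::vec_state(sv, 0)
    inp <- exogenous_input(runif(1, 0, 8), runif(1, 0, 200), runif(1, 0, 14))
    r <- runif(1, 0.5, 1.5)
    d_r <- derivatives(st, p, inp, resistance = r)
    d_c <- glucoloop:::cpp_derivatives(sv, glucoloop:::param_vec(p),
                                       inp$insulin_rate, inp$dextrose_rate,
                                       inp$enteral_CHO, r, 0)
    expect_equal(unname(d_r), as.numeric(d_c), tolerance = 1e-12)
  }
})

test_that("closed-form steady state satisfies the ODE and is monotone in insulin", {
  p <- nominal_test_patient()
  for (u in c(0.8, 1.5, 2.5)) {
    st <- steady_state_glucose(p, u, CHO = 7.5, full = TRUE)
    d <- derivatives(st, p, exogenous_input(u, 0, 7.5), resistance = 1)
    expect_lt(max(abs(d)), 1e-9)
  }
  g <- vapply(seq(0.6, 4, by = 0.2),
              function(u) steady_state_glucose(p, u, CHO = 7.5), numeric(1))
  expect_true(all(diff(g) < 0))
})

test_that("steady state errors when insulin cannot act", {
  p <- patient_params(S_IT = 1e-300, S_ID = 1e-300, S_IE = 1e-300)
  ## EGP0*w + CHO flux exceeds F01*w and insulin has no effect
  expect_error(steady_state_glucose(p, 5, CHO = 10), "no finite equilibrium")
  ## zero glucose appearance with suppressed production: no positive state
  p2 <- patient_params(EGP0 = 1e-300)
  expect_error(steady_state_glucose(p2, 3, CHO = 0), "no positive equilibrium")
})

test_that("steady state has a self-limited low-glucose branch", {
  p <- nominal_test_patient()
  ## high insulin with little feeding: equilibrium settles below the
  ## uptake saturation knee instead of draining to zero
  g <- steady_state_glucose(p, 6, CHO = 2)
  expect_gt(g, 0)
  expect_lt(g, 4.5)
  st <- steady_state_glucose(p, 6, CHO = 2, full = TRUE)
  d <- derivatives(st, p, exogenous_input(6, 0, 2), resistance = 1)
  expect_lt(max(abs(d)), 1e-9)
})

test_that("insulin_for_glucose inverts the steady state", {
  p <- nominal_test_patient()
  u <- insulin_for_glucose(p, 7, CHO = 7.5)
  expect_equal(steady_state_glucose(p, u, CHO = 7.5), 7, tolerance = 1e-6)
})

test_that("RK4 path matches a fine-step Euler oracle within 0.01 mM", {
  p <- nominal_test_patient()
  st <- steady_state_glucose(p, p$basal_insulin, CHO = 7.5, full = TRUE)
  s0 <- glucoloop:::state_vec(st)
  n_min <- 360  # 6-h scenario with a sustained insulin step
  path <- glucoloop:::cpp_path(s0, glucoloop:::param_vec(p),
                               3, 0, 7.5, 1, 0, 1, n_min)
  G_rk4 <- path[, 1] / (p$V_G * p$weight)
  G_euler <- euler_oracle(p, s0, u = 3, dex = 0, cho = 7.5, r = 1,
                          dt = 0.001, n_min = n_min)
  expect_lt(max(abs(G_rk4 - G_euler)), 0.01)
})

test_that("patient_step guards the step size and preserves zero dynamics", {
  p <- nominal_test_patient()
  st <- steady_state_glucose(p, 1.5, CHO = 7.5, full = TRUE)
  expect_error(patient_step(st, p, dt = 0), "dt")
  expect_error(patient_step(st, p, dt = 6), "dt")
  ## at its own equilibrium with matching inputs the state is unchanged
  out <- patient_step(st, p, exogenous_input(1.5, 0, 7.5), dt = 1, n = 60)
  expect_equal(plasma_glucose(out, p), plasma_glucose(st, p),
               tolerance = 1e-9)
})

test_that("states stay non-negative under random non-negative inputs", {
  p <- nominal_test_patient()
  set.seed(7)
  for (rep in 1:3) {
    st <- steady_state_glucose(p, 1.5, CHO = 7.5, full = TRUE)
    sv <- glucoloop:::state_vec(st)
    for (block in 1:48) {  # 48 h in 1-h blocks of constant random input
      u <- runif(1, 0, 10)
      cho <- sample(c(0, runif(1, 0, 14)), 1)
      sv <- as.numeric(glucoloop:::cpp_advance(
        sv, glucoloop:::param_vec(p), u, runif(1, 0, 50), cho,
        runif(1, 0.6, 1.4), 0, 1, 60L))
      expect_true(all(sv >= 0))
    }
  }
})

test_that("glucose mass is conserved when elimination and uptake are disabled", {
  eps <- 1e-300
  p <- patient_params(F01 = eps, S_IT = eps, S_ID = eps, S_IE = eps)
  st <- patient_state(Q1 = 100)
  sv <- glucoloop:::state_vec(st)
  hrs <- 6
  out <- as.numeric(glucoloop:::cpp_advance(
    sv, glucoloop:::param_vec(p), 0, 120, 0, 1, 0, 1, hrs * 60L))
  inputs <- (p$EGP0 * p$weight + 120 * 0.2 * 5.551 / 60) * hrs * 60
  expect_equal(out[1] + out[2], 100 + inputs, tolerance = 1e-3 * inputs)
})

test_that("48-h mean glucose is non-increasing in the constant insulin rate", {
  p <- nominal_test_patient()
  means <- vapply(seq(0, 10, by = 2), function(u) {
    st <- steady_state_glucose(p, p$basal_insulin, CHO = 7.5, full = TRUE)
    path <- glucoloop:::cpp_path(glucoloop:::state_vec(st),
                                 glucoloop:::param_vec(p),
                                 u, 0, 7.5, 1, 0, 1, 2880L)
    mean(path[, 1] / (p$V_G * p$weight))
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
})

test_that("cohorts are reproducible and satisfy the declared invariants", {
  c1 <- make_cohort(30, seed = 5)
  c2 <- make_cohort(30, seed = 5)
  expect_identical(c1, c2)
  for (p in c1) {
    expect_true(p$weight >= 40 && p$weight <= 200)
    rates <- c(p$V_G, p$k12, p$F01, p$EGP0, p$V_I, p$k_e,
               p$k_a1, p$k_a2, p$k_a3, p$S_IT, p$S_ID, p$S_IE)
    expect_true(all(rates > 0))
    expect_true(p$resistance$amplitude <= 0.4)
    expect_true(all(resistance_at(p$resistance, 0:2880) >= 0.2))
    expect_true(all(resistance_at(p$resistance, 0:2880) <= 3))
  }
})

test_that("cohort diabetes prevalence matches the configured probability", {
  co <- make_cohort(1000, seed = 1)
  frac <- mean(vapply(co, `[[`, logical(1), "diabetes"))
  expect_gt(frac, 0.41)
  expect_lt(frac, 0.51)
})

test_that("baseline steady glucose lies in 8-14 mM for >= 90% of subjects", {
  co <- make_cohort(200, seed = 3)
  g0 <- vapply(co, function(p)
    steady_state_glucose(p, p$basal_insulin, CHO = p$calib_CHO), numeric(1))
  expect_gte(mean(g0 >= 8 & g0 <= 14), 0.9)
})
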