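#include <Rcpp.h>
using namespace Rcpp;

// State layout (7 components):
//   0 Q1   accessible glucose mass, mmol
//   1 Q2   non-accessible glucose mass, mmol
//   2 I    plasma insulin, mU/L
//   3 x1   remote insulin action on transport, 1/min
//   4 x2   remote insulin action on disposal, 1/min
//   5 x3   remote insulin action on EGP, dimensionless
//   6 Qg   gut carbohydrate, g
//
// Parameter vector layout (14 components):
//   0 weight kg, 1 V_G L/kg, 2 k12 1/min, 3 F01 mmol/kg/min,
//   4 EGP0 mmol/kg/min, 5 V_I L/kg, 6 k_e 1/min,
//   7 k_a1, 8 k_a2, 9 k_a3 1/min,
//   10 S_IT, 11 S_ID (1/min per mU/L), 12 S_IE (per mU/L),
//   13 gut_tau min
//
// Exogenous inputs: u insulin U/h, dex 20% dextrose mL/h (0.2 g/mL),
// cho enteral carbohydrate g/h, r multiplicative insulin-sensitivity
// modulation, Fc additive glucose flux mmol/min (controller correction).

static const double MMOL_PER_G = 5.551;

static inline void deriv(const double* s, const double* p,
                         double u, double dex, double cho,
                         double r, double Fc, double* ds) {
  const double w = p[0], k12 = p[2], F01 = p[3], EGP0 = p[4],
               VI = p[5], ke = p[6], ka1 = p[7], ka2 = p[8], ka3 = p[9],
               SIT = p[10], SID = p[11], SIE = p[12], taug = p[13];
  const double Q1 = s[0], Q2 = s[1], I = s[2],
               x1 = s[3], x2 = s[4], x3 = s[5], Qg = s[6];
  const double ra_gut = MMOL_PER_G * Qg / taug;
  const double ra_dex = dex * 0.2 * MMOL_PER_G / 60.0;
  const double supp = (1.0 - x3) > 0.0 ? (1.0 - x3) : 0.0;
  // non-insulin-dependent uptake saturates: proportional to glucose
  // below 4.5 mM, constant above (hypoglycemia self-limitation)
  const double G = Q1 / (p[1] * w);
  const double f01c = (G < 4.5) ? F01 * w * G / 4.5 : F01 * w;
  ds[0] = -f01c - x1 * Q1 + k12 * Q2 + EGP0 * w * supp + ra_gut + ra_dex + Fc;
  ds[1] = x1 * Q1 - (k12 + x2) * Q2;
  ds[2] = u * (1000.0 / 60.0) / (VI * w) - ke * I;
  ds[3] = -ka1 * x1 + ka1 * SIT * r * I;
  ds[4] = -ka2 * x2 + ka2 * SID * r * I;
  ds[5] = -ka3 * x3 + ka3 * SIE * r * I;
  ds[6] = cho / 60.0 - Qg / taug;
}

// One classical 4th-order Runge-Kutta step; negatives clipped to zero.
static inline int rk4_step(double* s, const double* p, double u, double dex,
                           double cho, double r, double Fc, double dt) {
  double k1[7], k2[7], k3[7], k4[7], tmp[7];
  deriv(s, p, u, dex, cho, r, Fc, k1);
  for (int i = 0; i < 7; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  deriv(tmp, p, u, dex, cho, r, Fc, k2);
  for (int i = 0; i < 7; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  deriv(tmp, p, u, dex, cho, r, Fc, k3);
  for (int i = 0; i < 7; ++i) tmp[i] = s[i] + dt * k3[i];
  deriv(tmp, p, u, dex, cho, r, Fc, k4);
  int clipped = 0;
  for (int i = 0; i < 7; ++i) {
    s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (s[i] < 0.0) { s[i] = 0.0; ++clipped; }
  }
  return clipped;
}

// [[Rcpp::export]]
NumericVector cpp_derivatives(NumericVector state, NumericVector params,
                              double u, double dex, double cho,
                              double r, double Fc) {
  NumericVector out(7);
  deriv(REAL(state), REAL(params), u, dex, cho, r, Fc, REAL(out));
  return out;
}

// Advance n fixed RK4 steps under constant inputs; returns final state with
// the number of clipped components as attribute "n_clipped".
// [[Rcpp::export]]
NumericVector cpp_advance(NumericVector state, NumericVector params,
                          double u, double dex, double cho,
                          double r, double Fc, double dt, int n) {
  NumericVector out = clone(state);
  double* s = REAL(out);
  int clipped = 0;
  for (int k = 0; k < n; ++k)
    clipped += rk4_step(s, REAL(params), u, dex, cho, r, Fc, dt);
  out.attr("n_clipped") = clipped;
  return out;
}

// Full path: (n + 1) x 7 matrix including the initial state as row 1.
// [[Rcpp::export]]
NumericMatrix cpp_path(NumericVector state, NumericVector params,
                       double u, double dex, double cho,
                       double r, double Fc, double dt, int n) {
  NumericMatrix out(n + 1, 7);
  double s[7];
  for (int i = 0; i < 7; ++i) { s[i] = state[i]; out(0, i) = s[i]; }
  for (int k = 1; k <= n; ++k) {
    rk4_step(s, REAL(params), u, dex, cho, r, Fc, dt);
    for (int i = 0; i < 7; ++i) out(k, i) = s[i];
  }
  return out;
}

// Predicted plasma glucose at steps 1..n. `cho` is the internal model's
// fixed background carbohydrate prior, not measured nutrition: the
// controller is never told about actual enteral feeding.
// [[Rcpp::export]]
NumericVector cpp_predict_glucose(NumericVector state, NumericVector params,
                                  double u, double cho, double r, double Fc,
                                  double dt, int n) {
  NumericVector out(n);
  double s[7];
  for (int i = 0; i < 7; ++i) s[i] = state[i];
  const double vgw = params[1] * params[0];
  for (int k = 0; k < n; ++k) {
    rk4_step(s, REAL(params), u, 0.0, cho, r, Fc, dt);
    out[k] = s[0] / vgw;
  }
  return out;
}

// MPC cost over a grid of candidate constant insulin rates:
//   J(u) = sum_k (G_k(u) - target)^2 + lambda_u * (u - u_prev)^2
// with G_k on a dt-minute grid over an n*dt-minute horizon.
// [[Rcpp::export]]
NumericVector cpp_insulin_cost(NumericVector state, NumericVector params,
                               NumericVector u_grid, double cho, double r,
                               double Fc, double target, double lambda_u,
                               double u_prev, double dt, int n) {
  const int m = u_grid.size();
  NumericVector J(m);
  const double vgw = params[1] * params[0];
  for (int j = 0; j < m; ++j) {
    double s[7];
    for (int i = 0; i < 7; ++i) s[i] = state[i];
    double acc = 0.0;
    for (int k = 0; k < n; ++k) {
      rk4_step(s, REAL(params), u_grid[j], 0.0, cho, r, Fc, dt);
      const double g = s[0] / vgw - target;
      acc += g * g;
    }
    const double du = u_grid[j] - u_prev;
    J[j] = acc + lambda_u * du * du;
  }
  return J;
}
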