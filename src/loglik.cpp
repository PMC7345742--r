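#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// theta layout (length 20, per-year age scale):
//   4 transitions in order 0->1, 0->2, 1->0, 1->2;
//   within each: intercept, age, sex, hyp, diab.
//
// One elementary step = one month; the step matrix at exact age `age` (years)
// has live rows given by the multinomial-logit inversion with the stay
// category at logit 0, and the dead row (0,0,1).

static inline void step_rows(const double* th, double age, double sex,
                             double hyp, double diab, double row0[3],
                             double row1[3]) {
  double eta[4];
  for (int t = 0; t < 4; ++t) {
    const double* b = th + 5 * t;
    eta[t] = b[0] + b[1] * age + b[2] * sex + b[3] * hyp + b[4] * diab;
  }
  // row 0: stay, ->1 (eta[0]), ->2 (eta[1])
  {
    double m = eta[0] > 0.0 ? eta[0] : 0.0;
    if (eta[1] > m) m = eta[1];
    double w0 = std::exp(-m), w1 = std::exp(eta[0] - m),
           w2 = std::exp(eta[1] - m);
    double d = w0 + w1 + w2;
    row0[0] = w0 / d; row0[1] = w1 / d; row0[2] = w2 / d;
  }
  // row 1: ->0 (eta[2]), stay, ->2 (eta[3])
  {
    double m = eta[2] > 0.0 ? eta[2] : 0.0;
    if (eta[3] > m) m = eta[3];
    double w0 = std::exp(eta[2] - m), w1 = std::exp(-m),
           w2 = std::exp(eta[3] - m);
    double d = w0 + w1 + w2;
    row1[0] = w0 / d; row1[1] = w1 / d; row1[2] = w2 / d;
  }
}

// pairs: integer matrix, one row per observation pair, columns
//   0: a0  age in months at interval start
//   1: a1  age in months at interval end (a1 > a0)
//   2: s0  state at start (0/1)
//   3: s1  endpoint code:
//        0/1  live state observed at the end
//        2    death at the exact month a1: alive through a1-1, then the
//             dying transition in the final elementary interval
//        3    alive at a1, health state unknown (marginal over live states)
//        4    dead by a1 (cumulative: death anywhere in the gap)
//   4..6: sex, hyp, diab
// Returns the log interval probability of each pair. Row-stochastic products
// are accumulated in linear space (entries stay >= ~1e-300 for the <= 240
// month gaps of panel data) and logged once at the end; a structurally
// impossible pair yields -Inf.
// [[Rcpp::export]]
NumericVector cpp_pair_logliks(NumericVector theta, IntegerMatrix pairs) {
  if (theta.size() != 20) stop("theta must have length 20");
  const double* th = theta.begin();
  const int n = pairs.nrow();
  NumericVector out(n);
  double row0[3], row1[3];
  for (int i = 0; i < n; ++i) {
    const int a0 = pairs(i, 0), a1 = pairs(i, 1);
    const int s0 = pairs(i, 2), s1 = pairs(i, 3);
    const double sex = pairs(i, 4), hyp = pairs(i, 5), diab = pairs(i, 6);
    if (a1 <= a0) stop("pair %d: interval end not after start", i + 1);
    if (s0 != 0 && s0 != 1) { out[i] = R_NegInf; continue; }
    double v[3] = {0.0, 0.0, 0.0};
    v[s0] = 1.0;
    for (int am = a0; am < a1; ++am) {
      // exact-death endpoint: only the final month's dying transition counts,
      // so drop the mass already absorbed before the last factor
      if (s1 == 2 && am == a1 - 1) v[2] = 0.0;
      step_rows(th, am / 12.0, sex, hyp, diab, row0, row1);
      double n0 = v[0] * row0[0] + v[1] * row1[0];
      double n1 = v[0] * row0[1] + v[1] * row1[1];
      double n2 = v[0] * row0[2] + v[1] * row1[2] + v[2];
      v[0] = n0; v[1] = n1; v[2] = n2;
    }
    double p;
    if (s1 == 3) p = v[0] + v[1];
    else if (s1 == 4) p = v[2];
    else p = v[s1];
    out[i] = std::log(p);
  }
  return out;
}

// Sum of pair log-likelihoods; returns -Inf early if any pair is impossible.
// [[Rcpp::export]]
double cpp_dataset_loglik(NumericVector theta, IntegerMatrix pairs) {
  NumericVector ll = cpp_pair_logliks(theta, pairs);
  double s = 0.0;
  for (int i = 0; i < ll.size(); ++i) {
    if (!std::isfinite(ll[i])) return R_NegInf;
    s += ll[i];
  }
  return s;
}

// Log-likelihood and its exact gradient (per-year parameter scale) by
// forward sensitivity propagation: along v_{m+1} = v_m M_m the derivative
// rows follow dv_{m+1} = dv_m M_m + v_m dM_m, where dM_m is sparse (each
// coefficient perturbs one multinomial-logit row through the softmax
// Jacobian dq_k/deta_j = q_k (delta_kj - q_j)).
// [[Rcpp::export]]
List cpp_dataset_loglik_grad(NumericVector theta, IntegerMatrix pairs) {
  if (theta.size() != 20) stop("theta must have length 20");
  const double* th = theta.begin();
  const int n = pairs.nrow();
  double total = 0.0;
  NumericVector grad(20);
  double row0[3], row1[3];
  double dv[20][3], dvn[20][3];
  for (int i = 0; i < n; ++i) {
    const int a0 = pairs(i, 0), a1 = pairs(i, 1);
    const int s0 = pairs(i, 2), s1 = pairs(i, 3);
    const double sex = pairs(i, 4), hyp = pairs(i, 5), diab = pairs(i, 6);
    if (a1 <= a0) stop("pair %d: interval end not after start", i + 1);
    if (s0 != 0 && s0 != 1) {
      total = R_NegInf;
      continue;
    }
    double v[3] = {0.0, 0.0, 0.0};
    v[s0] = 1.0;
    for (int t = 0; t < 20; ++t) dv[t][0] = dv[t][1] = dv[t][2] = 0.0;
    for (int am = a0; am < a1; ++am) {
      if (s1 == 2 && am == a1 - 1) {
        v[2] = 0.0;
        for (int t = 0; t < 20; ++t) dv[t][2] = 0.0;
      }
      const double age = am / 12.0;
      step_rows(th, age, sex, hyp, diab, row0, row1);
      const double x[5] = {1.0, age, sex, hyp, diab};
      // propagate existing sensitivities through M
      for (int t = 0; t < 20; ++t) {
        dvn[t][0] = dv[t][0] * row0[0] + dv[t][1] * row1[0];
        dvn[t][1] = dv[t][0] * row0[1] + dv[t][1] * row1[1];
        dvn[t][2] = dv[t][0] * row0[2] + dv[t][1] * row1[2] + dv[t][2];
      }
      // source terms: dq/deta for the perturbed category of each block
      // block 0 (0->1): category state 1 of row 0
      const double s01[3] = {-row0[0] * row0[1], row0[1] * (1.0 - row0[1]),
                             -row0[2] * row0[1]};
      // block 1 (0->2): category state 2 of row 0
      const double s02[3] = {-row0[0] * row0[2], -row0[1] * row0[2],
                             row0[2] * (1.0 - row0[2])};
      // block 2 (1->0): category state 0 of row 1
      const double s10[3] = {row1[0] * (1.0 - row1[0]), -row1[1] * row1[0],
                             -row1[2] * row1[0]};
      // block 3 (1->2): category state 2 of row 1
      const double s12[3] = {-row1[0] * row1[2], -row1[1] * row1[2],
                             row1[2] * (1.0 - row1[2])};
      for (int c = 0; c < 5; ++c) {
        const double v0x = v[0] * x[c], v1x = v[1] * x[c];
        for (int k = 0; k < 3; ++k) {
          dvn[c][k]      += v0x * s01[k];
          dvn[5 + c][k]  += v0x * s02[k];
          dvn[10 + c][k] += v1x * s10[k];
          dvn[15 + c][k] += v1x * s12[k];
        }
      }
      for (int t = 0; t < 20; ++t) {
        dv[t][0] = dvn[t][0]; dv[t][1] = dvn[t][1]; dv[t][2] = dvn[t][2];
      }
      double n0 = v[0] * row0[0] + v[1] * row1[0];
      double n1 = v[0] * row0[1] + v[1] * row1[1];
      double n2 = v[0] * row0[2] + v[1] * row1[2] + v[2];
      v[0] = n0; v[1] = n1; v[2] = n2;
    }
    double p;
    if (s1 == 3) p = v[0] + v[1];
    else if (s1 == 4) p = v[2];
    else p = v[s1];
    if (!(p > 0.0) || !std::isfinite(total)) {
      total = R_NegInf;
      continue;
    }
    total += std::log(p);
    if (s1 == 3) {
      for (int t = 0; t < 20; ++t) grad[t] += (dv[t][0] + dv[t][1]) / p;
    } else {
      const int col = s1 == 4 ? 2 : s1;
      for (int t = 0; t < 20; ++t) grad[t] += dv[t][col] / p;
    }
  }
  return List::create(_["loglik"] = total, _["gradient"] = grad);
}
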