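#include <Rcpp.h>
using namespace Rcpp;

// SoftMax over (g*vx, g*vy, 0), stabilised by subtracting the max; also
// returns the log normaliser so log-probabilities never pass through an
// underflowing exponential.
static inline void softmax3(double g, double vx, double vy,
                            double &px, double &py, double &pz,
                            double &m, double &lse) {
  double ax = g * vx, ay = g * vy, az = 0.0;
  m = ax > ay ? ax : ay;
  if (az > m) m = az;
  double ex = std::exp(ax - m), ey = std::exp(ay - m), ez = std::exp(az - m);
  double s = ex + ey + ez;
  px = ex / s; py = ey / s; pz = ez / s;
  lse = std::log(s);
}

// log P(response) in log space: g*V_r - max - log sum exp
static inline double logp_resp(int r, double g, double vx, double vy,
                               double m, double lse) {
  double a = r == 0 ? g * vx : (r == 1 ? g * vy : 0.0);
  return a - m - lse;
}

// Trial-by-trial elemental / configural Rescorla-Wagner run.
// units/offsets: per-trial 0-based indices into the unit universe;
// utype: 0 = context, 1 = cue, 2 = conjunction (selects the alpha);
// alphas: (alpha_ctx, alpha_cue, alpha_cfg);
// resp: observed response per trial, 0 = X, 1 = Y, 2 = Z, -1 = none.
// One-step lookahead: the prediction for trial i uses learning through
// trial i-1; the update uses the scheduled outcome, never the response.
// [[Rcpp::export]]
List rw_core(IntegerVector units, IntegerVector offsets, IntegerVector utype,
             int n_universe, NumericVector alphas, double beta_us,
             double beta_nous, double g, IntegerVector lamX,
             IntegerVector lamY, IntegerVector resp, bool traj,
             bool beta_per_trial) {
  int n = lamX.size();
  std::vector<double> VX(n_universe, 0.0), VY(n_universe, 0.0);
  NumericVector tVX, tVY, tEX, tEY, tPX, tPY, tPZ;
  if (traj) {
    tVX = NumericVector(n); tVY = NumericVector(n);
    tEX = NumericVector(n); tEY = NumericVector(n);
    tPX = NumericVector(n); tPY = NumericVector(n); tPZ = NumericVector(n);
  }
  double L = 0.0;
  bool have_resp = resp.size() == n;
  for (int i = 0; i < n; ++i) {
    double vx = 0.0, vy = 0.0;
    for (int k = offsets[i]; k < offsets[i + 1]; ++k) {
      vx += VX[units[k]];
      vy += VY[units[k]];
    }
    double px, py, pz, mx, lse;
    softmax3(g, vx, vy, px, py, pz, mx, lse);
    if (have_resp && resp[i] >= 0) {
      L -= logp_resp(resp[i], g, vx, vy, mx, lse);
    }
    double ex = (double)lamX[i] - vx;
    double ey = (double)lamY[i] - vy;
    bool us = lamX[i] == 1 || lamY[i] == 1;
    double bx = beta_per_trial ? (us ? beta_us : beta_nous)
                               : (lamX[i] == 1 ? beta_us : beta_nous);
    double by = beta_per_trial ? (us ? beta_us : beta_nous)
                               : (lamY[i] == 1 ? beta_us : beta_nous);
    for (int k = offsets[i]; k < offsets[i + 1]; ++k) {
      double a = alphas[utype[units[k]]];
      VX[units[k]] += a * bx * ex;
      VY[units[k]] += a * by * ey;
    }
    if (traj) {
      tVX[i] = vx; tVY[i] = vy; tEX[i] = ex; tEY[i] = ey;
      tPX[i] = px; tPY[i] = py; tPZ[i] = pz;
    }
  }
  if (traj) {
    return List::create(_["L"] = L, _["V_X"] = tVX, _["V_Y"] = tVY,
                        _["err_X"] = tEX, _["err_Y"] = tEY,
                        _["p_X"] = tPX, _["p_Y"] = tPY, _["p_Z"] = tPZ);
  }
  return List::create(_["L"] = L);
}

// Trial-by-trial Pearce configural run.
// cfg: 0-based configuration index per trial; ratio: m x m matrix of the
// squared overlap n_ab^2 / (n_a n_b); similarity S = ratio^(d/2)
// elementwise (exact for even d).
// The prediction on trial i is the similarity-weighted sum of the
// associative strengths of all configurations; configurations not yet
// encountered hold strength 0, so first-trial registration is numerically
// neutral. Only the current configuration's strength is updated.
// [[Rcpp::export]]
List pearce_core(IntegerVector cfg, NumericMatrix ratio, double d,
                 double alpha, double beta_us, double beta_nous, double g,
                 IntegerVector lamX, IntegerVector lamY, IntegerVector resp,
                 bool traj, bool beta_per_trial) {
  int n = lamX.size();
  int m = ratio.nrow();
  std::vector<double> S(m * m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      S[i * m + j] = ratio(i, j) > 0.0 ? std::pow(ratio(i, j), d / 2.0) : 0.0;
  std::vector<double> VX(m, 0.0), VY(m, 0.0);
  NumericVector tVX, tVY, tEX, tEY, tPX, tPY, tPZ;
  if (traj) {
    tVX = NumericVector(n); tVY = NumericVector(n);
    tEX = NumericVector(n); tEY = NumericVector(n);
    tPX = NumericVector(n); tPY = NumericVector(n); tPZ = NumericVector(n);
  }
  double L = 0.0;
  bool have_resp = resp.size() == n;
  for (int i = 0; i < n; ++i) {
    int c = cfg[i];
    double vx = 0.0, vy = 0.0;
    for (int j = 0; j < m; ++j) {
      vx += S[c * m + j] * VX[j];
      vy += S[c * m + j] * VY[j];
    }
    double px, py, pz, mx, lse;
    softmax3(g, vx, vy, px, py, pz, mx, lse);
    if (have_resp && resp[i] >= 0) {
      L -= logp_resp(resp[i], g, vx, vy, mx, lse);
    }
    double ex = (double)lamX[i] - vx;
    double ey = (double)lamY[i] - vy;
    bool us = lamX[i] == 1 || lamY[i] == 1;
    double bx = beta_per_trial ? (us ? beta_us : beta_nous)
                               : (lamX[i] == 1 ? beta_us : beta_nous);
    double by = beta_per_trial ? (us ? beta_us : beta_nous)
                               : (lamY[i] == 1 ? beta_us : beta_nous);
    VX[c] += alpha * bx * ex;
    VY[c] += alpha * by * ey;
    if (traj) {
      tVX[i] = vx; tVY[i] = vy; tEX[i] = ex; tEY[i] = ey;
      tPX[i] = px; tPY[i] = py; tPZ[i] = pz;
    }
  }
  if (traj) {
    return List::create(_["L"] = L, _["V_X"] = tVX, _["V_Y"] = tVY,
                        _["err_X"] = tEX, _["err_Y"] = tEY,
                        _["p_X"] = tPX, _["p_Y"] = tPY, _["p_Z"] = tPZ);
  }
  return List::create(_["L"] = L);
}
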