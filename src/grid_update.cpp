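#include <Rcpp.h>
using namespace Rcpp;

// One fused Bayes update of the grid posterior: multiply the current mass
// by the trial likelihood, normalize, flush vanishing tail mass to exact
// zero (subnormals would slow all later arithmetic), and accumulate the
// threshold marginal on the fly (attached as attribute "theta_marg").
//
// trial_type: 0 = redirect, 1 = no_redirect
// outcome:    0 = anticipated, 1 = success, 2 = failure (not anticipated)
// Fts holds the logistic redirection component on the (theta, slope)
// sub-grid; idx_ts maps each node to its (theta, slope) cell (1-based).
// exec = (1-anticipation)(1-lapse), noant = 1-anticipation, antic =
// anticipation, all cached per node. Node order: theta fastest.
// [[Rcpp::export(name = ".grid_update_cpp")]]
NumericVector grid_update_cpp(NumericVector mass, NumericVector Fts,
                              IntegerVector idx_ts, NumericVector exec,
                              NumericVector noant, NumericVector antic,
                              int trial_type, int outcome, int n_theta) {
  R_xlen_t n = mass.size();
  NumericVector out(n);
  double z = 0.0;
  if (outcome == 0) {
    for (R_xlen_t i = 0; i < n; ++i) { out[i] = mass[i] * antic[i]; z += out[i]; }
  } else if (trial_type == 0) {
    if (outcome == 1) {
      for (R_xlen_t i = 0; i < n; ++i) {
        out[i] = mass[i] * exec[i] * Fts[idx_ts[i] - 1];
        z += out[i];
      }
    } else {
      for (R_xlen_t i = 0; i < n; ++i) {
        out[i] = mass[i] * (noant[i] - exec[i] * Fts[idx_ts[i] - 1]);
        z += out[i];
      }
    }
  } else {
    if (outcome == 1) {
      for (R_xlen_t i = 0; i < n; ++i) { out[i] = mass[i] * exec[i]; z += out[i]; }
    } else {
      for (R_xlen_t i = 0; i < n; ++i) {
        out[i] = mass[i] * (noant[i] - exec[i]);
        z += out[i];
      }
    }
  }
  if (!(z > 0) || !R_finite(z))
    stop("degenerate evidence: posterior mass vanished in the update");
  NumericVector tm(n_theta);
  R_xlen_t t = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = out[i] / z;
    if (v < 1e-280) v = 0.0;
    out[i] = v;
    tm[t] += v;
    if (++t == n_theta) t = 0;
  }
  out.attr("theta_marg") = tm;
  return out;
}

// Expected post-update Shannon entropy of the threshold marginal for each
// candidate dive lead time, assuming a redirection trial. The expectation
// runs over the three posterior-predictive outcomes (anticipated, success,
// failure); the likelihood factorizes over (theta, slope) x lapse x
// anticipation, so each candidate costs O(n_theta * n_slope).
// [[Rcpp::export(name = ".expected_entropy_cpp")]]
NumericVector expected_entropy_cpp(NumericVector mass, NumericVector theta,
                                   NumericVector slope, NumericVector exec,
                                   NumericVector noant, NumericVector antic,
                                   NumericVector candidates) {
  R_xlen_t n = mass.size();
  int nt = theta.size(), ns = slope.size(), nc = candidates.size();
  R_xlen_t nts = (R_xlen_t)nt * ns;
  std::vector<double> M1(nts, 0.0), m_ant(nt, 0.0), m_noant(nt, 0.0);
  double p_ant = 0.0;
  {
    R_xlen_t ts = 0, t = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double m = mass[i];
      M1[ts] += m * exec[i];
      double va = m * antic[i];
      m_ant[t] += va; p_ant += va;
      m_noant[t] += m * noant[i];
      if (++t == nt) t = 0;
      if (++ts == nts) ts = 0;
    }
  }
  // p * H(marg/p) = p log p - sum m log m
  double s_ant = 0.0;
  for (int t = 0; t < nt; ++t)
    if (m_ant[t] > 0) s_ant += m_ant[t] * std::log(m_ant[t]);
  double h_ant = (p_ant > 0) ? p_ant * std::log(p_ant) - s_ant : 0.0;

  NumericVector out(nc);
  std::vector<double> ms(nt);
  for (int c = 0; c < nc; ++c) {
    double tau = candidates[c];
    std::fill(ms.begin(), ms.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      double sl = slope[s];
      const double *M1s = &M1[(R_xlen_t)s * nt];
      for (int t = 0; t < nt; ++t) {
        double F = 1.0 / (1.0 + std::exp(-sl * (tau - theta[t])));
        ms[t] += F * M1s[t];
      }
    }
    double p_succ = 0.0, s_succ = 0.0, p_fail = 0.0, s_fail = 0.0;
    for (int t = 0; t < nt; ++t) {
      double a = ms[t];
      double b = m_noant[t] - a;
      if (b < 0) b = 0;
      p_succ += a; p_fail += b;
      if (a > 0) s_succ += a * std::log(a);
      if (b > 0) s_fail += b * std::log(b);
    }
    double h = h_ant;
    if (p_succ > 0) h += p_succ * std::log(p_succ) - s_succ;
    if (p_fail > 0) h += p_fail * std::log(p_fail) - s_fail;
    out[c] = h;
  }
  return out;
}
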