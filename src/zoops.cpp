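#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ZOOPS EM core for ungapped DNA motif discovery. Sequences arrive encoded as
// integer vectors over 0..3 (A,C,G,T); each sequence is passed in forward and
// reverse-complement orientation so both strands compete for the (at most one)
// site. All likelihoods are handled in log space.

static inline double logsumexp2(double a, double b) {
  double m = a > b ? a : b;
  if (m == R_NegInf) return R_NegInf;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// log-likelihood ratio of one site vs background
static inline double site_llr(const int* x, int off, int w,
                              const double* ltheta, const double* lbg) {
  double s = 0.0;
  for (int j = 0; j < w; ++j) {
    int b = x[off + j];
    s += ltheta[j + w * b] - lbg[b];
  }
  return s;
}

// One E-step: returns total LLR (relative to background-only model) and fills
// per-site posteriors when z is non-null.
static double estep(const std::vector<const int*>& fwd,
                    const std::vector<const int*>& rcv,
                    const std::vector<int>& len,
                    int w, const double* ltheta, const double* lbg,
                    double gamma,
                    std::vector<std::vector<double>>* zf,
                    std::vector<std::vector<double>>* zr) {
  int n = fwd.size();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = len[i] - w + 1;
    double lprior = std::log(gamma) - std::log(2.0 * m);
    double acc = R_NegInf;
    std::vector<double> lf(m), lr(m);
    for (int o = 0; o < m; ++o) {
      lf[o] = site_llr(fwd[i], o, w, ltheta, lbg) + lprior;
      acc = logsumexp2(acc, lf[o]);
    }
    for (int o = 0; o < m; ++o) {
      lr[o] = site_llr(rcv[i], o, w, ltheta, lbg) + lprior;
      acc = logsumexp2(acc, lr[o]);
    }
    double lnosite = (gamma < 1.0) ? std::log(1.0 - gamma) : R_NegInf;
    double ll = logsumexp2(acc, lnosite);
    total += ll;
    if (zf) {
      (*zf)[i].resize(m);
      (*zr)[i].resize(m);
      for (int o = 0; o < m; ++o) (*zf)[i][o] = std::exp(lf[o] - ll);
      for (int o = 0; o < m; ++o) (*zr)[i][o] = std::exp(lr[o] - ll);
    }
  }
  return total;
}

static void mstep(const std::vector<const int*>& fwd,
                  const std::vector<const int*>& rcv,
                  const std::vector<int>& len, int w,
                  const std::vector<std::vector<double>>& zf,
                  const std::vector<std::vector<double>>& zr,
                  const double* bg, double beta, double* theta) {
  std::vector<double> counts(w * 4, 0.0);
  double ztot = 0.0;
  int n = fwd.size();
  for (int i = 0; i < n; ++i) {
    int m = len[i] - w + 1;
    for (int o = 0; o < m; ++o) {
      double z = zf[i][o];
      if (z > 0) {
        ztot += z;
        for (int j = 0; j < w; ++j) counts[j + w * fwd[i][o + j]] += z;
      }
      z = zr[i][o];
      if (z > 0) {
        ztot += z;
        for (int j = 0; j < w; ++j) counts[j + w * rcv[i][o + j]] += z;
      }
    }
  }
  for (int j = 0; j < w; ++j) {
    double denom = ztot + beta;
    for (int b = 0; b < 4; ++b) {
      theta[j + w * b] = (counts[j + w * b] + beta * bg[b]) / denom;
    }
  }
}

static void encode_lists(List fwd, List rc,
                         std::vector<const int*>& pf,
                         std::vector<const int*>& pr,
                         std::vector<int>& len) {
  int n = fwd.size();
  pf.resize(n); pr.resize(n); len.resize(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = fwd[i];
    IntegerVector b = rc[i];
    pf[i] = INTEGER(a);
    pr[i] = INTEGER(b);
    len[i] = a.size();
  }
}

// [[Rcpp::export(name = ".zoops_em_cpp")]]
List zoops_em_cpp(List fwd, List rc, NumericMatrix theta0, double gamma,
                  NumericVector bg, int max_iter, double tol, double beta) {
  std::vector<const int*> pf, pr;
  std::vector<int> len;
  encode_lists(fwd, rc, pf, pr, len);
  int w = theta0.nrow();
  int n = pf.size();
  std::vector<double> theta(w * 4), ltheta(w * 4), lbg(4);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) theta[j + w * b] = theta0(j, b);
  for (int b = 0; b < 4; ++b) lbg[b] = std::log(bg[b]);

  std::vector<std::vector<double>> zf(n), zr(n);
  std::vector<double> trace;
  double prev = R_NegInf;
  for (int it = 0; it < max_iter; ++it) {
    for (int k = 0; k < w * 4; ++k) ltheta[k] = std::log(theta[k]);
    double llr = estep(pf, pr, len, w, ltheta.data(), lbg.data(), gamma, &zf, &zr);
    trace.push_back(llr);
    if (it > 0 && llr - prev < tol) { prev = llr; break; }
    prev = llr;
    mstep(pf, pr, len, w, zf, zr, bg.begin(), beta, theta.data());
  }
  // final E-step posteriors correspond to the last reported LLR
  for (int k = 0; k < w * 4; ++k) ltheta[k] = std::log(theta[k]);
  estep(pf, pr, len, w, ltheta.data(), lbg.data(), gamma, &zf, &zr);

  NumericMatrix theta_out(w, 4);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) theta_out(j, b) = theta[j + w * b];
  List zf_out(n), zr_out(n);
  for (int i = 0; i < n; ++i) {
    zf_out[i] = NumericVector(zf[i].begin(), zf[i].end());
    zr_out[i] = NumericVector(zr[i].begin(), zr[i].end());
  }
  return List::create(_["theta"] = theta_out,
                      _["llr_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["llr"] = prev,
                      _["zf"] = zf_out,
                      _["zr"] = zr_out);
}

// Screen candidate seeds: each seed w-mer becomes a sharp PWM (probability
// match_p on its own base) and is scored by one E-pass LLR over the data.
// Returns the LLR per seed.
// [[Rcpp::export(name = ".screen_seeds_cpp")]]
NumericVector screen_seeds_cpp(List fwd, List rc, IntegerMatrix seeds,
                               double gamma, NumericVector bg, double match_p) {
  std::vector<const int*> pf, pr;
  std::vector<int> len;
  encode_lists(fwd, rc, pf, pr, len);
  int w = seeds.ncol();
  int ns = seeds.nrow();
  double lmatch = std::log(match_p), lmiss = std::log((1.0 - match_p) / 3.0);
  std::vector<double> lbg(4);
  for (int b = 0; b < 4; ++b) lbg[b] = std::log(bg[b]);
  std::vector<double> ltheta(w * 4);
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    for (int j = 0; j < w; ++j) {
      int sb = seeds(s, j);
      for (int b = 0; b < 4; ++b) ltheta[j + w * b] = (b == sb) ? lmatch : lmiss;
    }
    out[s] = estep(pf, pr, len, w, ltheta.data(), lbg.data(), gamma, nullptr, nullptr);
  }
  return out;
}
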