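#include <Rcpp.h>
using namespace Rcpp;

// Two-state photon-by-photon hidden Markov model.
// State 1 = open, state 2 = closed. Between consecutive photons the state
// distribution relaxes analytically: for a 2-state generator with opening
// rate k_open (closed->open) and closing rate k_close (open->closed),
//   T(dt)[i][j] = pi_j * (1 - e) + delta_ij * e,  e = exp(-(k_open+k_close)dt)
// with pi = (k_open, k_close)/(k_open + k_close). At each photon the state
// probabilities are reweighted by the emission probability: an acceptor
// photon has probability E_state, a donor photon 1 - E_state.

// [[Rcpp::export]]
double hmm_loglik_cpp(NumericVector dt_s, IntegerVector acceptor,
                      double E_open, double E_closed,
                      double k_open, double k_close) {
  const int n = acceptor.size();
  if (n == 0) return 0.0;
  const double lam = k_open + k_close;
  const double pi1 = k_open / lam, pi2 = k_close / lam;
  double a1 = pi1, a2 = pi2;     // prior: equilibrium occupancies
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      const double e = std::exp(-lam * dt_s[i - 1]);
      const double tot = a1 + a2;   // == 1 after normalization below
      const double b1 = pi1 * (1.0 - e) * tot + a1 * e;
      const double b2 = pi2 * (1.0 - e) * tot + a2 * e;
      a1 = b1; a2 = b2;
    }
    const double e1 = acceptor[i] ? E_open : 1.0 - E_open;
    const double e2 = acceptor[i] ? E_closed : 1.0 - E_closed;
    a1 *= e1; a2 *= e2;
    const double s = a1 + a2;
    if (s <= 0.0 || !std::isfinite(s)) return -std::numeric_limits<double>::infinity();
    ll += std::log(s);
    a1 /= s; a2 /= s;
  }
  return ll;
}

// Summed log-likelihood over many bursts packed end-to-end.
// burst_start: 0-based index of each burst's first photon; dt_s has one
// entry per photon (dt to previous photon; the entry at each burst start
// is ignored).
// [[Rcpp::export]]
double hmm_loglik_multi_cpp(NumericVector dt_s, IntegerVector acceptor,
                            IntegerVector burst_start, IntegerVector burst_len,
                            double E_open, double E_closed,
                            double k_open, double k_close) {
  const double lam = k_open + k_close;
  const double pi1 = k_open / lam, pi2 = k_close / lam;
  double ll = 0.0;
  for (int b = 0; b < burst_start.size(); ++b) {
    double a1 = pi1, a2 = pi2;
    const int s0 = burst_start[b], len = burst_len[b];
    for (int i = 0; i < len; ++i) {
      const int k = s0 + i;
      if (i > 0) {
        const double e = std::exp(-lam * dt_s[k]);
        const double b1 = pi1 * (1.0 - e) + a1 * e;
        const double b2 = pi2 * (1.0 - e) + a2 * e;
        a1 = b1; a2 = b2;
      }
      const double e1 = acceptor[k] ? E_open : 1.0 - E_open;
      const double e2 = acceptor[k] ? E_closed : 1.0 - E_closed;
      a1 *= e1; a2 *= e2;
      const double s = a1 + a2;
      if (s <= 0.0 || !std::isfinite(s)) return -std::numeric_limits<double>::infinity();
      ll += std::log(s);
      a1 /= s; a2 /= s;
    }
  }
  return ll;
}

// Most probable state path (Viterbi) under the same model; returns
// 1 = open, 2 = closed per photon.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector dt_s, IntegerVector acceptor,
                              double E_open, double E_closed,
                              double k_open, double k_close) {
  const int n = acceptor.size();
  IntegerVector path(n);
  if (n == 0) return path;
  const double lam = k_open + k_close;
  const double pi1 = k_open / lam, pi2 = k_close / lam;
  std::vector<signed char> back1(n), back2(n);
  double d1 = std::log(pi1), d2 = std::log(pi2);
  {
    const double e1 = acceptor[0] ? E_open : 1.0 - E_open;
    const double e2 = acceptor[0] ? E_closed : 1.0 - E_closed;
    d1 += std::log(e1); d2 += std::log(e2);
  }
  for (int i = 1; i < n; ++i) {
    const double e = std::exp(-lam * dt_s[i]);
    const double t11 = pi1 * (1.0 - e) + e, t12 = pi2 * (1.0 - e);
    const double t21 = pi1 * (1.0 - e),     t22 = pi2 * (1.0 - e) + e;
    const double l11 = std::log(t11), l12 = std::log(t12);
    const double l21 = std::log(t21), l22 = std::log(t22);
    double n1, n2;
    if (d1 + l11 >= d2 + l21) { n1 = d1 + l11; back1[i] = 1; }
    else                      { n1 = d2 + l21; back1[i] = 2; }
    if (d1 + l12 >= d2 + l22) { n2 = d1 + l12; back2[i] = 1; }
    else                      { n2 = d2 + l22; back2[i] = 2; }
    const double e1 = acceptor[i] ? E_open : 1.0 - E_open;
    const double e2 = acceptor[i] ? E_closed : 1.0 - E_closed;
    d1 = n1 + std::log(e1);
    d2 = n2 + std::log(e2);
  }
  int s = (d1 >= d2) ? 1 : 2;
  path[n - 1] = s;
  for (int i = n - 1; i > 0; --i) {
    s = (s == 1) ? back1[i] : back2[i];
    path[i - 1] = s;
  }
  return path;
}
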