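#include <Rcpp.h>
using namespace Rcpp;

// Forward recursion over latent states {F, C, dead} for a set of
// encounter histories. Probability arrays are column-major over
// (cohort, time, state): phi and psi have time = interval 1..T-1,
// p has time = occasion 1..T. psi is the move probability (origin ->
// other state), conditional on survival; survival acts first, then
// movement, then detection at the destination.

// [[Rcpp::export]]
NumericVector ms_history_probs_cpp(IntegerMatrix obs, IntegerVector first,
                                   IntegerVector cohort, NumericVector phi,
                                   NumericVector psi, NumericVector p,
                                   int n_coh) {
  const int n = obs.nrow(), T = obs.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    const int f = first[i] - 1, c = cohort[i] - 1;
    double a0 = 0.0, a1 = 0.0, dead = 0.0;
    const int s0 = obs(i, f) - 1;
    if (s0 == 0) a0 = 1.0; else a1 = 1.0;
    for (int t = f; t < T - 1; t++) {
      const double phiF = phi[c + n_coh * (t + (T - 1) * 0)];
      const double phiC = phi[c + n_coh * (t + (T - 1) * 1)];
      const double mF = psi[c + n_coh * (t + (T - 1) * 0)];
      const double mC = psi[c + n_coh * (t + (T - 1) * 1)];
      const double nF = a0 * phiF * (1.0 - mF) + a1 * phiC * mC;
      const double nC = a0 * phiF * mF + a1 * phiC * (1.0 - mC);
      const double nDead = dead + a0 * (1.0 - phiF) + a1 * (1.0 - phiC);
      const double pF = p[c + n_coh * ((t + 1) + T * 0)];
      const double pC = p[c + n_coh * ((t + 1) + T * 1)];
      const int o = obs(i, t + 1);
      if (o == 1) {
        a0 = nF * pF; a1 = 0.0; dead = 0.0;
      } else if (o == 2) {
        a0 = 0.0; a1 = nC * pC; dead = 0.0;
      } else {
        a0 = nF * (1.0 - pF); a1 = nC * (1.0 - pC); dead = nDead;
      }
    }
    out[i] = a0 + a1 + dead;
  }
  return out;
}

// -2 * sum(count * log(prob)); returns R_PosInf if any history has
// non-positive probability.

// [[Rcpp::export]]
double ms_neg2ll_cpp(IntegerMatrix obs, IntegerVector first,
                     IntegerVector cohort, NumericVector count,
                     NumericVector phi, NumericVector psi, NumericVector p,
                     int n_coh) {
  NumericVector pr = ms_history_probs_cpp(obs, first, cohort, phi, psi, p,
                                          n_coh);
  double s = 0.0;
  for (int i = 0; i < pr.size(); i++) {
    if (!(pr[i] > 0.0)) return R_PosInf;
    s += count[i] * std::log(pr[i]);
  }
  return -2.0 * s;
}
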