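#include <Rcpp.h>
using namespace Rcpp;

// Per-sample stepping of the three-state folding CTMC.
// States: 0 = folded (pre-pseudoknot), 1 = unfolded, 2 = folded (pseudoknot).
// Transition probability per sample is 1 - exp(-k * dt); on each refolding
// event the molecule commits to the pseudoknot state with probability p_pk.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".ctmc_step_path")]]
IntegerVector ctmc_step_path(NumericVector ku_pre, NumericVector ku_pk,
                             NumericVector kf, NumericVector p_pk,
                             double dt, int init_state) {
  int n = ku_pre.size();
  IntegerVector state(n);
  int s = init_state;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    state[i] = s;
    double u = R::unif_rand();
    if (s == 1) {               // unfolded -> may refold
      if (u < 1.0 - std::exp(-kf[i] * dt)) {
        s = (R::unif_rand() < p_pk[i]) ? 2 : 0;
      }
    } else if (s == 0) {        // pre-pseudoknot -> may unfold
      if (u < 1.0 - std::exp(-ku_pre[i] * dt)) s = 1;
    } else {                    // pseudoknot -> may unfold
      if (u < 1.0 - std::exp(-ku_pk[i] * dt)) s = 1;
    }
  }
  return state;
}

// Two-state Viterbi decoder with fixed Gaussian emission levels and a
// symmetric per-sample switching prior. Returns 0 (folded level) / 1
// (unfolded level) per sample.
// [[Rcpp::export(name = ".viterbi_two_state")]]
IntegerVector viterbi_two_state(NumericVector x, double mu0, double mu1,
                                double sd, double p_switch) {
  int n = x.size();
  IntegerVector path(n);
  if (n == 0) return path;
  double log_stay = std::log(1.0 - p_switch);
  double log_switch = std::log(p_switch);
  std::vector<double> d0(n), d1(n);
  std::vector<signed char> b0(n, 0), b1(n, 0);
  double inv2s2 = 1.0 / (2.0 * sd * sd);
  d0[0] = -(x[0] - mu0) * (x[0] - mu0) * inv2s2 + std::log(0.5);
  d1[0] = -(x[0] - mu1) * (x[0] - mu1) * inv2s2 + std::log(0.5);
  for (int i = 1; i < n; ++i) {
    double e0 = -(x[i] - mu0) * (x[i] - mu0) * inv2s2;
    double e1 = -(x[i] - mu1) * (x[i] - mu1) * inv2s2;
    double a00 = d0[i - 1] + log_stay, a10 = d1[i - 1] + log_switch;
    if (a00 >= a10) { d0[i] = a00 + e0; b0[i] = 0; }
    else            { d0[i] = a10 + e0; b0[i] = 1; }
    double a11 = d1[i - 1] + log_stay, a01 = d0[i - 1] + log_switch;
    if (a11 >= a01) { d1[i] = a11 + e1; b1[i] = 1; }
    else            { d1[i] = a01 + e1; b1[i] = 0; }
  }
  int s = (d1[n - 1] > d0[n - 1]) ? 1 : 0;
  for (int i = n - 1; i >= 0; --i) {
    path[i] = s;
    s = (s == 0) ? b0[i] : b1[i];
  }
  return path;
}
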