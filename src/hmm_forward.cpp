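#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward recursion for the two-state autozygosity HMM.
// States: IBD (autozygous) and non-IBD. Transitions over genetic distance
// d (Morgans): P(IBD->IBD) = e^{-a d} + (1 - e^{-a d}) f,
// P(non->IBD) = (1 - e^{-a d}) f. Chains restart (stationary (f, 1-f))
// wherever new_chain is true (chromosome boundaries).
// e_ibd / e_non are the per-marker emission probabilities of the observed
// genotype under each state (1 for missing genotypes).

// [[Rcpp::export]]
double hmm_forward_cpp(NumericVector e_ibd, NumericVector e_non,
                       NumericVector d, LogicalVector new_chain,
                       double f, double a) {
  int n = e_ibd.size();
  if (f < 0.0) f = 0.0;
  if (f > 0.999) f = 0.999;
  if (a < 1e-8) a = 1e-8;
  double ll = 0.0, ai = 0.0, an = 1.0;
  for (int i = 0; i < n; ++i) {
    double pi, pn;
    if (new_chain[i]) {
      pi = f;
      pn = 1.0 - f;
    } else {
      double r = std::exp(-a * d[i]);
      pi = ai * (r + (1.0 - r) * f) + an * ((1.0 - r) * f);
      pn = ai * ((1.0 - r) * (1.0 - f)) + an * (r + (1.0 - r) * (1.0 - f));
    }
    double wi = pi * e_ibd[i];
    double wn = pn * e_non[i];
    double s = wi + wn;
    if (!(s > 0.0)) return R_NegInf;
    ll += std::log(s);
    ai = wi / s;
    an = wn / s;
  }
  return ll;
}
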