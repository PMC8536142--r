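#include <Rcpp.h>
using namespace Rcpp;

// Simulate a base sequence from an order-0 or order-1 Markov model.
// init: length-4 probabilities for the first base (A,C,G,T);
// trans: 4x4 row-stochastic transition matrix (ignored when order == 0).
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
std::string simulate_markov_cpp(int n, NumericVector init,
                                NumericMatrix trans, int order) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string out(n, 'A');
  double cinit[4];
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) { acc += init[j]; cinit[j] = acc; }
  double ctrans[4][4];
  if (order == 1) {
    for (int i = 0; i < 4; ++i) {
      acc = 0.0;
      for (int j = 0; j < 4; ++j) { acc += trans(i, j); ctrans[i][j] = acc; }
    }
  }
  int state = 0;
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    const double *cum = (order == 1 && i > 0) ? ctrans[state] : cinit;
    int j = 0;
    while (j < 3 && u > cum[j]) ++j;
    state = j;
    out[i] = bases[j];
  }
  return out;
}
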