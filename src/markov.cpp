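#include <Rcpp.h>
using namespace Rcpp;

// Per-sample first-order Markov state path over a fixed state set.
// cum_trans: one row-cumulative transition matrix per time block;
// block: 1-based block index per emitted sample. Uses R's RNG so the
// path is reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector markov_path_cpp(int n, IntegerVector block, List cum_trans,
                              int init_state) {
  std::vector<NumericMatrix> P;
  P.reserve(cum_trans.size());
  for (int b = 0; b < cum_trans.size(); ++b)
    P.push_back(as<NumericMatrix>(cum_trans[b]));
  IntegerVector out(n);
  int s = init_state;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    const NumericMatrix &M = P[block[i] - 1];
    double u = unif_rand();
    int k = 0;
    while (k < M.ncol() - 1 && u > M(s - 1, k)) ++k;
    s = k + 1;
    out[i] = s;
  }
  return out;
}
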