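#include <Rcpp.h>
using namespace Rcpp;

// Sample a discrete-time Markov chain over 3 states with one transition
// matrix per light phase. cum_light / cum_dark hold row-wise cumulative
// transition probabilities (3 x 3, last column == 1). `dark` flags, per
// epoch, whether the DARK matrix governs the transition OUT of that epoch.
// `u` holds one uniform draw per transition (length n - 1 for n epochs).
// Returns 1-based state codes; epoch 1 is `init` itself.
// [[Rcpp::export]]
IntegerVector markov_path_cpp(NumericMatrix cum_light, NumericMatrix cum_dark,
                              IntegerVector dark, int init, NumericVector u) {
  int n = u.size() + 1;
  IntegerVector out(n);
  int s = init - 1;
  out[0] = init;
  for (int i = 1; i < n; ++i) {
    double uu = u[i - 1];
    int ns = 0;
    if (dark[i - 1]) {
      while (ns < 2 && uu > cum_dark(s, ns)) ++ns;
    } else {
      while (ns < 2 && uu > cum_light(s, ns)) ++ns;
    }
    s = ns;
    out[i] = s + 1;
  }
  return out;
}
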