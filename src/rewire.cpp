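#include <Rcpp.h>
using namespace Rcpp;

// Maslov-Sneppen double-edge swap on a symmetric weight matrix.
// Edge list (ei, ej) is 1-based (upper triangle). Each accepted swap rewires
// (a,b),(c,d) -> (a,d),(c,b), the two weights travelling with their original
// edge slot. Degrees are preserved exactly. Draws from R's RNG so that
// set.seed() in R governs the result.

// [[Rcpp::export]]
NumericMatrix rewire_double_swap(NumericMatrix w, IntegerVector ei,
                                 IntegerVector ej, int n_attempts) {
  NumericMatrix out = clone(w);
  int n_edges = ei.size();
  std::vector<int> a(ei.begin(), ei.end());
  std::vector<int> b(ej.begin(), ej.end());
  RNGScope scope;
  for (int t = 0; t < n_attempts; ++t) {
    int e1 = (int)(unif_rand() * n_edges);
    int e2 = (int)(unif_rand() * n_edges);
    if (e1 >= n_edges) e1 = n_edges - 1;
    if (e2 >= n_edges) e2 = n_edges - 1;
    if (e1 == e2) continue;
    int x1 = a[e1], y1 = b[e1];
    int x2 = a[e2], y2 = b[e2];
    // randomly flip the orientation of the second edge
    if (unif_rand() < 0.5) { int tmp = x2; x2 = y2; y2 = tmp; }
    // propose (x1,y2) and (x2,y1)
    if (x1 == y2 || x2 == y1) continue;          // self-loop
    if (x1 == x2 || y1 == y2) continue;          // no-op / duplicate source
    if (out(x1 - 1, y2 - 1) > 0 || out(x2 - 1, y1 - 1) > 0) continue;
    double w1 = out(x1 - 1, y1 - 1);
    double w2 = out(x2 - 1, y2 - 1);
    out(x1 - 1, y1 - 1) = 0; out(y1 - 1, x1 - 1) = 0;
    out(x2 - 1, y2 - 1) = 0; out(y2 - 1, x2 - 1) = 0;
    out(x1 - 1, y2 - 1) = w1; out(y2 - 1, x1 - 1) = w1;
    out(x2 - 1, y1 - 1) = w2; out(y1 - 1, x2 - 1) = w2;
    a[e1] = x1; b[e1] = y2;
    a[e2] = x2; b[e2] = y1;
  }
  return out;
}
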