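#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive scan over all size-n subsets of {0, ..., N-1} in lexicographic
// order. Strict-improvement updates keep the lexicographically first optimum,
// and the first subset seeds `best` so an all-(-Inf) instance still returns
// a deterministic answer. logm is the element-wise log of the dissimilarity
// matrix; only i < j entries are read.
// [[Rcpp::export]]
List exact_enumerate_cpp(NumericMatrix logm, int n, bool maximize) {
  const int N = logm.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  double best = 0.0;
  bool first = true;
  IntegerVector best_idx(n);
  unsigned long long iter = 0;

  for (;;) {
    double obj = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *col = &logm(0, idx[i]);
      for (int j = i + 1; j < n; ++j) obj += col[idx[j]];
    }
    if (first || (maximize ? obj > best : obj < best)) {
      best = obj;
      for (int i = 0; i < n; ++i) best_idx[i] = idx[i] + 1;
      first = false;
    }
    if ((++iter & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();

    int p = n - 1;
    while (p >= 0 && idx[p] == N - n + p) --p;
    if (p < 0) break;
    ++idx[p];
    for (int q = p + 1; q < n; ++q) idx[q] = idx[q - 1] + 1;
  }
  return List::create(_["indices"] = best_idx, _["objective"] = best);
}
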