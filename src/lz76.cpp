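#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv 1976 complexity (exhaustive production counting) of a binary
// sequence, following the Kaspar & Schuster scanning algorithm.
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1, i = 0, k = 1, l = 1, k_max = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > k_max) k_max = k;
      ++i;
      if (i == l) {
        ++c;
        l += k_max;
        if (l + 1 > n) break;
        i = 0;
        k = 1;
        k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
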