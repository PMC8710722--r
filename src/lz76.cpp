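#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// LZ76 exhaustive phrase count, Kaspar-Schuster style scan.
// The final (possibly incomplete) phrase counts as one.
static int lz76_count_core(const int* s, int n) {
  if (n <= 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, k_max = 1;
  if (n == 1) return 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      k++;
      if (l + k > n) { c++; break; }
    } else {
      if (k > k_max) k_max = k;
      i++;
      if (i == l) {
        c++;
        l += k_max;
        if (l + 1 > n) break;
        i = 0; k = 1; k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Independent reference parser: builds each phrase directly from the
// definition, extending it while it still occurs as a substring of the
// text before its last symbol (naive search).
static int lz76_brute_core(const int* s, int n) {
  if (n <= 0) return 0;
  int c = 0, h = 0;
  while (h < n) {
    int j = h;
    while (j < n) {
      int len = j - h + 1;
      bool found = false;
      for (int p = 0; p + len <= j && !found; ++p) {
        bool match = true;
        for (int t = 0; t < len; ++t) {
          if (s[p + t] != s[h + t]) { match = false; break; }
        }
        if (match) found = true;
      }
      if (!found) break;
      j++;
    }
    c++;
    if (j >= n) break;  // final incomplete phrase
    h = j + 1;
  }
  return c;
}

// [[Rcpp::export]]
int lz76_count_cpp(IntegerVector symbols) {
  return lz76_count_core(INTEGER(symbols), symbols.size());
}

// [[Rcpp::export]]
int lz76_brute_cpp(IntegerVector symbols) {
  return lz76_brute_core(INTEGER(symbols), symbols.size());
}

// [[Rcpp::export]]
List lz76_sweep_cpp(int max_len, int alphabet) {
  double total = 0, mismatches = 0;
  std::vector<int> s;
  for (int len = 1; len <= max_len; ++len) {
    s.assign(len, 0);
    while (true) {
      if (lz76_count_core(s.data(), len) != lz76_brute_core(s.data(), len)) {
        mismatches += 1;
      }
      total += 1;
      int pos = len - 1;
      while (pos >= 0 && s[pos] == alphabet - 1) { s[pos] = 0; pos--; }
      if (pos < 0) break;
      s[pos]++;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["total"] = total, _["mismatches"] = mismatches);
}
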