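#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment (Needleman-Wunsch) with linear gap penalty.
// Traceback ties are broken deterministically: diagonal, then up (gap in the
// reference), then left (gap in the query), so identical inputs always give
// identical alignments.
// [[Rcpp::export]]
List nw_align_cpp(std::string query, std::string ref,
                  double match, double mismatch, double gap) {
  const int n = query.size();
  const int m = ref.size();
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 0 = diag, 1 = up, 2 = left
  for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; P(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = S(i - 1, j - 1) +
        (query[i - 1] == ref[j - 1] ? match : mismatch);
      double up = S(i - 1, j) + gap;
      double left = S(i, j - 1) + gap;
      double best = diag;
      int ptr = 0;
      if (up > best) { best = up; ptr = 1; }
      if (left > best) { best = left; ptr = 2; }
      S(i, j) = best;
      P(i, j) = ptr;
    }
  }
  std::string aq, ar;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int ptr = P(i, j);
    if (i > 0 && j > 0 && ptr == 0) {
      aq.push_back(query[i - 1]); ar.push_back(ref[j - 1]); --i; --j;
    } else if (i > 0 && ptr == 1) {
      aq.push_back(query[i - 1]); ar.push_back('-'); --i;
    } else {
      aq.push_back('-'); ar.push_back(ref[j - 1]); --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());
  return List::create(_["score"] = S(n, m),
                      _["aligned_query"] = aq,
                      _["aligned_ref"] = ar);
}
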