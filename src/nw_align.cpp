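#include <Rcpp.h>
#include <string>
#include <vector>

// Global (Needleman-Wunsch) alignment statistics under the fixed scoring
// match +1, mismatch 0, linear gap -1. Among maximum-score alignments the
// one maximizing the number of matches is selected; this lexicographic DP
// is well defined because the order (score, then matches) is preserved
// under addition of a common suffix contribution. Identity and coverage
// are fully determined by (score, matches):
//   gap columns  G = matches - score
//   aligned pairs A = (la + lb - G) / 2
//   identity = matches / (A + G), coverage = A / min(la, lb).

// [[Rcpp::export(name = ".nw_align_stats")]]
Rcpp::IntegerVector nw_align_stats(std::string a, std::string b) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0) Rcpp::stop("sequences must be non-empty");
  // rows indexed by j (over b); rolling arrays over i
  std::vector<int> S(lb + 1), M(lb + 1), Sp(lb + 1), Mp(lb + 1);
  for (int j = 0; j <= lb; ++j) { Sp[j] = -j; Mp[j] = 0; }
  for (int i = 1; i <= la; ++i) {
    S[0] = -i; M[0] = 0;
    const char ca = a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      const int ms = (ca == b[j - 1]) ? 1 : 0;
      int bs = Sp[j - 1] + ms, bm = Mp[j - 1] + ms;   // diagonal
      int us = Sp[j] - 1, um = Mp[j];                 // gap in b
      if (us > bs || (us == bs && um > bm)) { bs = us; bm = um; }
      int ls = S[j - 1] - 1, lm = M[j - 1];           // gap in a
      if (ls > bs || (ls == bs && lm > bm)) { bs = ls; bm = lm; }
      S[j] = bs; M[j] = bm;
    }
    std::swap(S, Sp); std::swap(M, Mp);
  }
  return Rcpp::IntegerVector::create(Sp[lb], Mp[lb]);
}
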