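#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap costs and
// penalized end gaps: match +1, mismatch -1, gap -2. Identity is
// matches / alignment columns. Traceback tie-break: diagonal, then up
// (gap in the second sequence), then left; the tie-break is part of the
// function's definition so an independent implementation can agree
// exactly.
// [[Rcpp::export(name = ".nw_identity")]]
List nw_identity(std::string a, std::string b,
                 double match = 1.0, double mismatch = -1.0,
                 double gap = -2.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  // full DP matrix needed for traceback; n, m are ORF-sized
  std::vector<std::vector<double> > dp(n + 1, std::vector<double>(m + 1));
  for (int j = 0; j <= m; ++j) dp[0][j] = gap * j;
  for (int i = 1; i <= n; ++i) {
    dp[i][0] = gap * i;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double best = dp[i - 1][j - 1] + s;
      double up = dp[i - 1][j] + gap;
      double left = dp[i][j - 1] + gap;
      if (up > best) best = up;
      if (left > best) best = left;
      dp[i][j] = best;
    }
  }
  int i = n, j = m;
  long matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        dp[i][j] == dp[i - 1][j - 1] +
                        ((a[i - 1] == b[j - 1]) ? match : mismatch)) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && dp[i][j] == dp[i - 1][j] + gap) {
      --i;
    } else {
      --j;
    }
    ++columns;
  }
  return List::create(_["score"] = dp[n][m],
                      _["matches"] = (double)matches,
                      _["columns"] = (double)columns,
                      _["identity"] = 100.0 * matches / columns);
}
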