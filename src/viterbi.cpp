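#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global sequence-to-profile Viterbi alignment in log2 space.
//
// States: M_j / I_j / D_j for profile columns j = 1..n, plus a begin state
// treated as M_0. Transition row j governs moves out of column j; row 0 is
// the begin row. Match emissions score log2(e_j(a)/q_a); insert emissions
// are at background (log-odds 0); delete states emit nothing. The
// alignment must consume the whole sequence and all n columns; the final
// transition to the end is not scored.
//
// ltrans: (n+1) x 7 matrix of log2 transition probabilities with column
// order MM, MI, MD, IM, II, DM, DD. lemit: n x m matrix of match
// log-odds, lemit(j-1, i-1) for column j emitting sequence residue i.
// [[Rcpp::export]]
double viterbi_score_cpp(NumericMatrix lemit, NumericMatrix ltrans) {
  const int n = lemit.nrow();
  const int m = lemit.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  const int MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6;

  // DP tables indexed [j][i], j = 0..n, i = 0..m
  NumericMatrix M(n + 1, m + 1), I(n + 1, m + 1), D(n + 1, m + 1);
  std::fill(M.begin(), M.end(), NEG);
  std::fill(I.begin(), I.end(), NEG);
  std::fill(D.begin(), D.end(), NEG);
  M(0, 0) = 0.0;  // begin

  for (int j = 0; j <= n; ++j) {
    for (int i = 0; i <= m; ++i) {
      if (j > 0) {  // M and D consume a column
        if (i > 0) {
          double best = M(j - 1, i - 1) + ltrans(j - 1, MM);
          double v = I(j - 1, i - 1) + ltrans(j - 1, IM);
          if (v > best) best = v;
          v = D(j - 1, i - 1) + ltrans(j - 1, DM);
          if (v > best) best = v;
          M(j, i) = best + lemit(j - 1, i - 1);
        }
        double bestd = M(j - 1, i) + ltrans(j - 1, MD);
        double v = D(j - 1, i) + ltrans(j - 1, DD);
        if (v > bestd) bestd = v;
        D(j, i) = bestd;
      }
      if (i > 0) {  // I consumes a residue, stays at column j
        double besti = M(j, i - 1) + ltrans(j, MI);
        double v = I(j, i - 1) + ltrans(j, II);
        if (v > besti) besti = v;
        I(j, i) = besti;  // insert emission at background: log-odds 0
      }
    }
  }
  double best = M(n, m);
  if (I(n, m) > best) best = I(n, m);
  if (D(n, m) > best) best = D(n, m);
  return best;
}
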