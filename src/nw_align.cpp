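#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap penalties.
// Scoring follows the usual DNA conventions of the EMBOSS needle tool:
// match +5, mismatch -4, and a gap of length L costs gap_open + L * gap_extend
// (end gaps are penalized: the alignment is fully global). 'N' is
// mismatch-neutral: it scores 0 against anything. Traceback ties are broken
// deterministically: diagonal, then up (gap in the reference), then left.

static inline double subscore(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return 0.0;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string query, std::string ref,
                  double match = 5.0, double mismatch = -4.0,
                  double gap_open = 10.0, double gap_extend = 0.5) {
  const int n = query.size(), m = ref.size();
  if (n == 0 || m == 0) stop("sequences must be nonempty");
  const double NEG = -std::numeric_limits<double>::infinity();
  const double open1 = gap_open + gap_extend;  // cost of a length-1 gap

  // M: ends in aligned pair; X: ends with gap in ref (consumes query);
  // Y: ends with gap in query (consumes ref).
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = -(gap_open + j * gap_extend);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subscore(query[i - 1], ref[j - 1], match, mismatch);
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      double best = dM;
      if (dX > best) best = dX;
      if (dY > best) best = dY;
      M[at(i, j)] = best + s;

      double xo = M[at(i - 1, j)] - open1;
      double xe = X[at(i - 1, j)] - gap_extend;
      double xy = Y[at(i - 1, j)] - open1;
      X[at(i, j)] = std::max(std::max(xo, xe), xy);

      double yo = M[at(i, j - 1)] - open1;
      double ye = Y[at(i, j - 1)] - gap_extend;
      double yx = X[at(i, j - 1)] - open1;
      Y[at(i, j)] = std::max(std::max(yo, ye), yx);
    }
  }

  // traceback; state preference on ties: M (diagonal), X (up), Y (left)
  int i = n, j = m;
  char state;
  double fM = M[at(n, m)], fX = X[at(n, m)], fY = Y[at(n, m)];
  double score = fM; state = 'M';
  if (fX > score) { score = fX; state = 'X'; }
  if (fY > score) { score = fY; state = 'Y'; }

  std::string aq, ar;
  aq.reserve(n + m);
  ar.reserve(n + m);
  while (i > 0 || j > 0) {
    if (state == 'M') {
      double s = subscore(query[i - 1], ref[j - 1], match, mismatch);
      double prev = M[at(i, j)] - s;
      aq.push_back(query[i - 1]);
      ar.push_back(ref[j - 1]);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] == prev) state = 'M';
      else if (X[at(i, j)] == prev) state = 'X';
      else state = 'Y';
    } else if (state == 'X') {
      aq.push_back(query[i - 1]);
      ar.push_back('-');
      double cur = X[at(i, j)];
      --i;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] - open1 == cur) state = 'M';
      else if (X[at(i, j)] - gap_extend == cur) state = 'X';
      else state = 'Y';
    } else {
      aq.push_back('-');
      ar.push_back(ref[j - 1]);
      double cur = Y[at(i, j)];
      --j;
      if (i == 0 && j == 0) break;
      if (M[at(i, j)] - open1 == cur) state = 'M';
      else if (Y[at(i, j)] - gap_extend == cur) state = 'Y';
      else state = 'X';
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());
  return List::create(_["score"] = score, _["aligned_query"] = aq,
                      _["aligned_ref"] = ar);
}
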