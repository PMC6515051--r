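// Global (Needleman-Wunsch/Gotoh) protein alignment with affine gaps:
// a gap of length L costs gap_open + L * gap_extend.  Traceback is
// deterministic with tie preference diagonal > up (gap in b) > left
// (gap in a).  Sequences arrive as 1-based integer vectors indexing the
// substitution matrix.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(const IntegerVector& a, const IntegerVector& b,
              const NumericMatrix& sm, double gap_open,
              double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  const double open1 = gap_open + gap_extend;

  // DP matrices: 0 = M (diag), 1 = Ix (up, consumes a), 2 = Iy (left)
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> Ix((n + 1) * (m + 1), NEG);
  std::vector<double> Iy((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) Ix[at(i, 0)] = -open1 - (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Iy[at(0, j)] = -open1 - (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(M[at(i - 1, j - 1)],
                             std::max(Ix[at(i - 1, j - 1)],
                                      Iy[at(i - 1, j - 1)]));
      M[at(i, j)] = sm(a[i - 1] - 1, b[j - 1] - 1) + prev;
      Ix[at(i, j)] = std::max(M[at(i - 1, j)] - open1,
                              std::max(Ix[at(i - 1, j)] - gap_extend,
                                       Iy[at(i - 1, j)] - open1));
      Iy[at(i, j)] = std::max(M[at(i, j - 1)] - open1,
                              std::max(Iy[at(i, j - 1)] - gap_extend,
                                       Ix[at(i, j - 1)] - open1));
    }
  }

  double best = M[at(n, m)];
  int state = 0;
  if (Ix[at(n, m)] > best) { best = Ix[at(n, m)]; state = 1; }
  if (Iy[at(n, m)] > best) { best = Iy[at(n, m)]; state = 2; }

  // traceback
  std::vector<int> ops;                 // 0 diag, 1 up, 2 left
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) { state = (i > 0) ? 1 : 2; continue; }
      ops.push_back(0);
      double target = M[at(i, j)] - sm(a[i - 1] - 1, b[j - 1] - 1);
      --i; --j;
      if (std::abs(M[at(i, j)] - target) < eps) state = 0;
      else if (std::abs(Ix[at(i, j)] - target) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back(1);
      double cur = Ix[at(i, j)];
      --i;
      if (std::abs(M[at(i, j)] - (cur + open1)) < eps) state = 0;
      else if (std::abs(Ix[at(i, j)] - (cur + gap_extend)) < eps) state = 1;
      else state = 2;
    } else {
      ops.push_back(2);
      double cur = Iy[at(i, j)];
      --j;
      if (std::abs(M[at(i, j)] - (cur + open1)) < eps) state = 0;
      else if (std::abs(Iy[at(i, j)] - (cur + gap_extend)) < eps) state = 2;
      else state = 1;
    }
  }

  const int L = ops.size();
  IntegerVector ai(L), bi(L);          // 0 = gap, else 1-based position
  int pa = 1, pb = 1;
  for (int k = L - 1, c = 0; k >= 0; --k, ++c) {
    if (ops[k] == 0) { ai[c] = pa++; bi[c] = pb++; }
    else if (ops[k] == 1) { ai[c] = pa++; bi[c] = 0; }
    else { ai[c] = 0; bi[c] = pb++; }
  }
  return List::create(_["score"] = best, _["a_pos"] = ai, _["b_pos"] = bi);
}
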