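#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

// Alignment DP kernels. Substitution scores arrive as a 27x27 matrix indexed
// by (uppercase letter - 'A'); rows/cols for letters absent from the scoring
// scheme hold a large negative sentinel so misuse surfaces as a bad score,
// not silent garbage.

static inline int aidx(char c) { return c - 'A'; }

static double sw_one(const std::string& a, const std::string& b,
                     const IntegerMatrix& sub, double gap_open,
                     double gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> H(n + 1, 0.0), Hprev(n + 1, 0.0), F(n + 1, NEG);
  double best = 0.0;
  std::vector<int> bi(n);
  for (int j = 0; j < n; ++j) bi[j] = aidx(b[j]);
  for (int i = 1; i <= m; ++i) {
    std::swap(H, Hprev);
    H[0] = 0.0;
    double E = NEG;
    const int ai = aidx(a[i - 1]);
    for (int j = 1; j <= n; ++j) {
      // gap of length k costs gap_open + k * gap_extend
      E = std::max(H[j - 1] - (gap_open + gap_extend), E - gap_extend);
      F[j] = std::max(Hprev[j] - (gap_open + gap_extend), F[j] - gap_extend);
      double h = Hprev[j - 1] + (double)sub(ai, bi[j - 1]);
      h = std::max(h, E);
      h = std::max(h, F[j]);
      h = std::max(h, 0.0);
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
double sw_score_cpp(std::string a, std::string b, IntegerMatrix sub,
                    double gap_open, double gap_extend) {
  return sw_one(a, b, sub, gap_open, gap_extend);
}

// All-vs-all local alignment scores; rows index A, columns index B.
// [[Rcpp::export]]
NumericMatrix sw_score_all_cpp(CharacterVector A, CharacterVector B,
                               IntegerMatrix sub, double gap_open,
                               double gap_extend) {
  const int na = A.size(), nb = B.size();
  std::vector<std::string> as(na), bs(nb);
  for (int i = 0; i < na; ++i) as[i] = Rcpp::as<std::string>(A[i]);
  for (int j = 0; j < nb; ++j) bs[j] = Rcpp::as<std::string>(B[j]);
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j)
      out(i, j) = sw_one(as[i], bs[j], sub, gap_open, gap_extend);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Global affine-gap profile alignment over a precomputed column-pair score
// matrix S (m rows for profile 1, n columns for profile 2). Terminal gaps
// are penalized like internal ones. Returns the optimal score and the
// aligned path as two index vectors (0 = gap in that profile).
// [[Rcpp::export]]
List nw_profile_path_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = -1e18;
  // state 0 = match, 1 = gap in profile 2 (profile 1 consumed), 2 = gap in 1
  std::vector<std::vector<double>> M(m + 1, std::vector<double>(n + 1, NEG));
  std::vector<std::vector<double>> X(m + 1, std::vector<double>(n + 1, NEG));
  std::vector<std::vector<double>> Y(m + 1, std::vector<double>(n + 1, NEG));
  // traceback: which predecessor state fed each cell/state
  std::vector<std::vector<signed char>> tM(m + 1, std::vector<signed char>(n + 1, -1));
  std::vector<std::vector<signed char>> tX(m + 1, std::vector<signed char>(n + 1, -1));
  std::vector<std::vector<signed char>> tY(m + 1, std::vector<signed char>(n + 1, -1));

  M[0][0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[i][0] = -(gap_open + i * gap_extend);
    tX[i][0] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    Y[0][j] = -(gap_open + j * gap_extend);
    tY[0][j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // match: deterministic preference M > X > Y on ties
      double bm = M[i - 1][j - 1]; signed char sm = 0;
      if (X[i - 1][j - 1] > bm) { bm = X[i - 1][j - 1]; sm = 1; }
      if (Y[i - 1][j - 1] > bm) { bm = Y[i - 1][j - 1]; sm = 2; }
      M[i][j] = bm + S(i - 1, j - 1); tM[i][j] = sm;
      // gap in profile 2 (consume row i)
      double bx = M[i - 1][j] - (gap_open + gap_extend); signed char sx = 0;
      if (X[i - 1][j] - gap_extend > bx) { bx = X[i - 1][j] - gap_extend; sx = 1; }
      if (Y[i - 1][j] - (gap_open + gap_extend) > bx) {
        bx = Y[i - 1][j] - (gap_open + gap_extend); sx = 2;
      }
      X[i][j] = bx; tX[i][j] = sx;
      // gap in profile 1 (consume column j)
      double by = M[i][j - 1] - (gap_open + gap_extend); signed char sy = 0;
      if (X[i][j - 1] - (gap_open + gap_extend) > by) {
        by = X[i][j - 1] - (gap_open + gap_extend); sy = 1;
      }
      if (Y[i][j - 1] - gap_extend > by) { by = Y[i][j - 1] - gap_extend; sy = 2; }
      Y[i][j] = by; tY[i][j] = sy;
    }
  }
  double best = M[m][n]; int state = 0;
  if (X[m][n] > best) { best = X[m][n]; state = 1; }
  if (Y[m][n] > best) { best = Y[m][n]; state = 2; }

  std::vector<int> p1, p2;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char prev = tM[i][j];
      p1.push_back(i); p2.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      signed char prev = tX[i][j];
      p1.push_back(i); p2.push_back(0);
      --i; state = prev;
    } else {
      signed char prev = tY[i][j];
      p1.push_back(0); p2.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["score"] = best,
                      _["path1"] = IntegerVector(p1.begin(), p1.end()),
                      _["path2"] = IntegerVector(p2.begin(), p2.end()));
}
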