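#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine gap convention used throughout the package: a gap run of length L
// costs gap_open + (L - 1) * gap_ext (penalties given as positive numbers).
// Traceback tie-break: diagonal, then up (gap in b), then left (gap in a).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_affine_cpp")]]
List nw_affine_cpp(std::string a, std::string b,
                   double match, double mismatch,
                   double gap_open, double gap_ext) {
  int n = a.size(), m = b.size();
  // state matrices: M diagonal, X gap in b (consume a, "up"), Y gap in a ("left")
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[idx(i, 0)] = -(gap_open + (i - 1) * gap_ext);
  for (int j = 1; j <= m; ++j) Y[idx(0, j)] = -(gap_open + (j - 1) * gap_ext);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double dM = M[idx(i - 1, j - 1)], dX = X[idx(i - 1, j - 1)], dY = Y[idx(i - 1, j - 1)];
      double best = dM; if (dX > best) best = dX; if (dY > best) best = dY;
      M[idx(i, j)] = best + s;

      double xo = M[idx(i - 1, j)] - gap_open;
      double xy = Y[idx(i - 1, j)] - gap_open;
      double xe = X[idx(i - 1, j)] - gap_ext;
      double xb = xo; if (xy > xb) xb = xy; if (xe > xb) xb = xe;
      X[idx(i, j)] = xb;

      double yo = M[idx(i, j - 1)] - gap_open;
      double yx = X[idx(i, j - 1)] - gap_open;
      double ye = Y[idx(i, j - 1)] - gap_ext;
      double yb = yo; if (yx > yb) yb = yx; if (ye > yb) yb = ye;
      Y[idx(i, j)] = yb;
    }
  }

  // traceback, preferring state M over X over Y wherever scores tie
  std::string ra, rb;
  int i = n, j = m;
  int state; // 0 = M, 1 = X, 2 = Y
  {
    double sM = M[idx(n, m)], sX = X[idx(n, m)], sY = Y[idx(n, m)];
    state = (sM >= sX && sM >= sY) ? 0 : (sX >= sY ? 1 : 2);
  }
  double score = (state == 0) ? M[idx(n, m)] : (state == 1 ? X[idx(n, m)] : Y[idx(n, m)]);

  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) break; // cannot happen with valid DP
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      double target = M[idx(i, j)] - ((a[i - 1] == b[j - 1]) ? match : mismatch);
      --i; --j;
      if (M[idx(i, j)] == target) state = 0;
      else if (X[idx(i, j)] == target) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      double cur = X[idx(i, j)];
      --i;
      if (M[idx(i, j)] - gap_open == cur) state = 0;
      else if (X[idx(i, j)] - gap_ext == cur) state = 1;
      else state = 2;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      double cur = Y[idx(i, j)];
      --j;
      if (M[idx(i, j)] - gap_open == cur) state = 0;
      else if (X[idx(i, j)] - gap_open == cur) state = 1;
      else state = 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}

// Profile-profile global alignment with affine gaps. Profiles are
// (n_residues + 1) x L frequency matrices, last row = gap frequency.
// Column score is expected sum-of-pairs between the two columns; aligning a
// column against an all-gap column costs the affine penalties scaled by the
// column's non-gap occupancy. Returns an integer path: 0 = both advance,
// 1 = profile A advances (gap column inserted in B), 2 = B advances.
// [[Rcpp::export(name = ".profile_align_cpp")]]
IntegerVector profile_align_cpp(NumericMatrix pa, NumericMatrix pb,
                                double match, double mismatch,
                                double gap_open, double gap_ext) {
  int R = pa.nrow() - 1; // residues (last row is gap)
  int n = pa.ncol(), m = pb.ncol();

  // expected substitution score between column u of A and v of B
  std::vector<double> colsc(n * m);
  for (int u = 0; u < n; ++u) {
    double ga = pa(R, u);
    for (int v = 0; v < m; ++v) {
      double s = 0.0, dot = 0.0;
      for (int r = 0; r < R; ++r) dot += pa(r, u) * pb(r, v);
      double occa = 1.0 - ga, occb = 1.0 - pb(R, v);
      s = dot * match + (occa * occb - dot) * mismatch;
      // residue-vs-gap pairs within the merged column treated as extensions
      s -= (occa * pb(R, v) + occb * ga) * gap_ext;
      colsc[u * m + v] = s;
    }
  }

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[idx(i, 0)] = -(gap_open + (i - 1) * gap_ext);
  for (int j = 1; j <= m; ++j) Y[idx(0, j)] = -(gap_open + (j - 1) * gap_ext);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = colsc[(i - 1) * m + (j - 1)];
      double dM = M[idx(i - 1, j - 1)], dX = X[idx(i - 1, j - 1)], dY = Y[idx(i - 1, j - 1)];
      double best = dM; if (dX > best) best = dX; if (dY > best) best = dY;
      M[idx(i, j)] = best + s;

      double xb = M[idx(i - 1, j)] - gap_open;
      double t = Y[idx(i - 1, j)] - gap_open; if (t > xb) xb = t;
      t = X[idx(i - 1, j)] - gap_ext; if (t > xb) xb = t;
      X[idx(i, j)] = xb;

      double yb = M[idx(i, j - 1)] - gap_open;
      t = X[idx(i, j - 1)] - gap_open; if (t > yb) yb = t;
      t = Y[idx(i, j - 1)] - gap_ext; if (t > yb) yb = t;
      Y[idx(i, j)] = yb;
    }
  }

  std::vector<int> path;
  int i = n, j = m, state;
  {
    double sM = M[idx(n, m)], sX = X[idx(n, m)], sY = Y[idx(n, m)];
    state = (sM >= sX && sM >= sY) ? 0 : (sX >= sY ? 1 : 2);
  }
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back(0);
      double target = M[idx(i, j)] - colsc[(i - 1) * m + (j - 1)];
      --i; --j;
      if (M[idx(i, j)] == target) state = 0;
      else if (X[idx(i, j)] == target) state = 1;
      else state = 2;
    } else if (state == 1) {
      path.push_back(1);
      double cur = X[idx(i, j)];
      --i;
      if (M[idx(i, j)] - gap_open == cur) state = 0;
      else if (X[idx(i, j)] - gap_ext == cur) state = 1;
      else state = 2;
    } else {
      path.push_back(2);
      double cur = Y[idx(i, j)];
      --j;
      if (M[idx(i, j)] - gap_open == cur) state = 0;
      else if (X[idx(i, j)] - gap_open == cur) state = 1;
      else state = 2;
    }
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}
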