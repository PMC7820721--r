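#include <Rcpp.h>
using namespace Rcpp;

// Classic DTW with local cost |a_i - b_j|, unit steps (match/insert/delete),
// endpoints anchored, no warping window. Two-row dynamic program.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<double> prev(m), cur(m);
  prev[0] = std::abs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::abs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::abs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      cur[j] = best + std::abs(a[i] - b[j]);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// All-pairs DTW between the rows of a matrix.
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(NumericMatrix x) {
  const int n = x.nrow(), L = x.ncol();
  NumericMatrix d(n, n);
  std::vector<double> prev(L), cur(L);
  for (int p = 0; p < n; ++p) {
    for (int q = p + 1; q < n; ++q) {
      NumericMatrix::Row a = x(p, _), b = x(q, _);
      prev[0] = std::abs(a[0] - b[0]);
      for (int j = 1; j < L; ++j) prev[j] = prev[j - 1] + std::abs(a[0] - b[j]);
      for (int i = 1; i < L; ++i) {
        cur[0] = prev[0] + std::abs(a[i] - b[0]);
        for (int j = 1; j < L; ++j) {
          double best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
          cur[j] = best + std::abs(a[i] - b[j]);
        }
        std::swap(prev, cur);
      }
      d(p, q) = d(q, p) = prev[L - 1];
    }
  }
  return d;
}

// Index of the nearest seed point for each query point (squared Euclidean).
// [[Rcpp::export]]
IntegerVector nearest_seed_cpp(NumericVector px, NumericVector py,
                               NumericVector sx, NumericVector sy) {
  const int n = px.size(), k = sx.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < k; ++j) {
      double dx = px[i] - sx[j], dy = py[i] - sy[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

// Center-to-center Euclidean distance from every cell to the nearest cell
// whose mask value is TRUE. Brute force over mask cells (exact).
// [[Rcpp::export]]
NumericMatrix nearest_cell_distance_cpp(LogicalMatrix mask, double cell_size) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> tr, tc;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c)) { tr.push_back(r); tc.push_back(c); }
  if (tr.empty()) stop("class absent from raster: distance undefined");
  NumericMatrix out(nr, nc);
  const int k = tr.size();
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c)) { out(r, c) = 0.0; continue; }
      double best = R_PosInf;
      for (int j = 0; j < k; ++j) {
        double dr = r - tr[j], dc = c - tc[j];
        double d2 = dr * dr + dc * dc;
        if (d2 < best) best = d2;
      }
      out(r, c) = std::sqrt(best) * cell_size;
    }
  }
  return out;
}
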