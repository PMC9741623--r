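// Exact maximum-weight bipartite matching (rectangular assignment).
//
// The LP relaxation of the assignment polytope is integral (totally
// unimodular constraints), so the combinatorial optimum solves the
// matching program exactly. Implemented as the O(n^3) Hungarian
// algorithm with potentials on the square zero-padded cost matrix.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Reusable workspace to avoid per-call allocations in batched solves.
struct HungarianWS {
  std::vector<double> u, v, minv;
  std::vector<int> p, way;
  std::vector<char> used;
  void resize(int n, int mcols) {
    u.assign(n + 1, 0.0);
    v.assign(mcols + 1, 0.0);
    minv.assign(mcols + 1, 0.0);
    p.assign(mcols + 1, 0);
    way.assign(mcols + 1, 0);
    used.assign(mcols + 1, 0);
  }
};

// Min-cost matching of all n rows into m >= n columns (rectangular
// Hungarian with potentials, O(n^2 m)). a(i, j) is the cost of pairing
// row i with column j. On exit p[j] = matched row for column j (1-based,
// 0 = free).
static void hungarian_rect(const double* a, const int n, const int m,
                           HungarianWS& ws) {
  const double INF = std::numeric_limits<double>::infinity();
  ws.resize(n, m);
  std::vector<double>& u = ws.u;
  std::vector<double>& v = ws.v;
  std::vector<double>& minv = ws.minv;
  std::vector<int>& p = ws.p;
  std::vector<int>& way = ws.way;
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::fill(ws.used.begin(), ws.used.end(), 0);
    do {
      ws.used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (!ws.used[j]) {
          // column-major a: entry (i0-1, j-1)
          double cur = a[(size_t)(j - 1) * n + (i0 - 1)] - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      }
      for (int j = 0; j <= m; ++j) {
        if (ws.used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
}

// Solve max-weight injective assignment on rectangular nonnegative F.
// Fills rows/cols (1-based index pairs) and returns the optimal value.
// The shorter side is matched completely, which is optimal because all
// scores are nonnegative.
static double match_one(const arma::mat& F, std::vector<int>& rows,
                        std::vector<int>& cols, HungarianWS& ws,
                        arma::mat& buf) {
  const int r = F.n_rows, c = F.n_cols;
  rows.clear(); cols.clear();
  double value = 0.0;
  if (r <= c) {
    buf = -F;  // rows into columns
    hungarian_rect(buf.memptr(), r, c, ws);
    for (int j = 0; j < c; ++j) {
      int i = ws.p[j + 1];
      if (i > 0) {
        value += F(i - 1, j);
        rows.push_back(i);
        cols.push_back(j + 1);
      }
    }
  } else {
    buf = -F.t();  // columns into rows
    hungarian_rect(buf.memptr(), c, r, ws);
    for (int j = 0; j < r; ++j) {
      int i = ws.p[j + 1];
      if (i > 0) {
        value += F(j, i - 1);
        rows.push_back(j + 1);
        cols.push_back(i);
      }
    }
  }
  return value;
}

// [[Rcpp::export(name = ".hungarian_cpp")]]
List hungarian_cpp(const arma::mat& F) {
  if (F.n_elem == 0) stop("empty matrix");
  if (!F.is_finite()) stop("non-finite entries in score matrix");
  if (F.min() < 0) stop("negative entries in score matrix");
  std::vector<int> rows, cols;
  HungarianWS ws;
  arma::mat buf;
  double value = match_one(F, rows, cols, ws, buf);
  IntegerMatrix assignment(rows.size(), 2);
  for (size_t k = 0; k < rows.size(); ++k) {
    assignment(k, 0) = rows[k];
    assignment(k, 1) = cols[k];
  }
  colnames(assignment) = CharacterVector::create("row", "col");
  return List::create(_["value"] = value, _["assignment"] = assignment);
}

// Batched matching over m hidden sets: S is |X| x (m*c), column block k
// holding the scores against hidden set k. Returns per-set matching
// values and the matched (row, col) pairs, zero-padded to min(|X|, c).
// [[Rcpp::export(name = ".match_batch_cpp")]]
List match_batch_cpp(const arma::mat& S, const int m, const int c) {
  const int r = S.n_rows;
  if ((int)S.n_cols != m * c) stop("score matrix has wrong width");
  const int nmatch = std::min(r, c);
  NumericVector values(m);
  IntegerMatrix mrows(m, nmatch), mcols(m, nmatch);
  std::vector<int> rows, cols;
  HungarianWS ws;
  arma::mat buf, block;
  for (int k = 0; k < m; ++k) {
    block = S.cols(k * c, (k + 1) * c - 1);
    values[k] = match_one(block, rows, cols, ws, buf);
    for (size_t t = 0; t < rows.size() && (int)t < nmatch; ++t) {
      mrows(k, t) = rows[t];
      mcols(k, t) = cols[t];
    }
  }
  return List::create(_["values"] = values, _["rows"] = mrows,
                      _["cols"] = mcols);
}

// Matching features for a whole minibatch: Sall stacks the per-sample
// score matrices vertically (nw rows each). Returns a B x m value
// matrix and the matched pairs per (sample, hidden set).
// [[Rcpp::export(name = ".match_minibatch_cpp")]]
List match_minibatch_cpp(const arma::mat& Sall, const int nw, const int m,
                         const int c) {
  if ((int)Sall.n_cols != m * c) stop("score matrix has wrong width");
  if (Sall.n_rows % nw != 0) stop("row count not a multiple of nw");
  const int B = Sall.n_rows / nw;
  const int nmatch = std::min(nw, c);
  NumericMatrix values(B, m);
  IntegerVector dims = IntegerVector::create(B, m, nmatch);
  IntegerVector arows(B * m * nmatch, 0), acols(B * m * nmatch, 0);
  std::vector<int> rows, cols;
  HungarianWS ws;
  arma::mat buf, block;
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < m; ++k) {
      block = Sall.submat(b * nw, k * c, (b + 1) * nw - 1,
                          (k + 1) * c - 1);
      values(b, k) = match_one(block, rows, cols, ws, buf);
      for (size_t t = 0; t < rows.size() && (int)t < nmatch; ++t) {
        // index into [B x m x nmatch] array, column-major
        size_t off = b + (size_t)k * B + (size_t)t * B * m;
        arows[off] = rows[t];
        acols[off] = cols[t];
      }
    }
  }
  arows.attr("dim") = dims;
  acols.attr("dim") = dims;
  return List::create(_["values"] = values, _["rows"] = arows,
                      _["cols"] = acols);
}
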