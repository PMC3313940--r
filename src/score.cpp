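#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Batched running-sum word scores.
//
// z: genes x words matrix of column-standardized word counts.
// orders: genes x B matrix of 1-based gene indices, one column per gene
//   ordering (column 1 = the observed ranking, further columns = rank
//   permutations of the null).
// Returns words x B matrix with entry (w, b) = max over prefixes k of
//   sum_{i<=k} z[orders[i,b], w] / sqrt(G).

// [[Rcpp::export]]
NumericMatrix run_max_scores(NumericMatrix z, IntegerMatrix orders) {
  const int G = z.nrow(), W = z.ncol(), B = orders.ncol();
  if (orders.nrow() != G) stop("orders must have one row per gene");
  NumericMatrix out(W, B);
  const double inv_sqrt_g = 1.0 / std::sqrt((double)G);
  for (int b = 0; b < B; ++b) {
    const int* ord = &orders(0, b);
    for (int w = 0; w < W; ++w) {
      const double* zc = &z(0, w);
      double s = 0.0, best = R_NegInf;
      for (int i = 0; i < G; ++i) {
        s += zc[ord[i] - 1];
        if (s > best) best = s;
      }
      out(w, b) = best * inv_sqrt_g;
    }
    if (b % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Sparse equivalent of run_max_scores for non-negative count-like matrices.
//
// Standardization is done internally: for a column with mean mu and
// population sd s, a zero entry contributes the constant (0 - mu)/s, so the
// running sum declines linearly between the (few) genes where the word
// occurs and its prefix maximum can only be attained at an occurrence or at
// the very first position.  The matrix is therefore walked gene-major over
// its non-zero entries only, which for 7-mers cuts the work ~15-fold.
// Columns with zero variance (unscorable words) yield NA.
//
// x: genes x words, non-negative (counts, presence, or per-kb rates).
// orders: genes x B permutations (1-based); column 1 is typically the
//   observed ranking.

// [[Rcpp::export]]
NumericMatrix sparse_run_max_scores(NumericMatrix x, IntegerMatrix orders) {
  const int G = x.nrow(), W = x.ncol(), B = orders.ncol();
  if (orders.nrow() != G) stop("orders must have one row per gene");

  std::vector<double> zero_z(W), inv_sd(W), mu(W);
  std::vector<char> ok(W);
  for (int w = 0; w < W; ++w) {
    const double* xc = &x(0, w);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < G; ++i) {
      if (xc[i] < 0) stop("sparse scorer requires non-negative values");
      s += xc[i];
      s2 += xc[i] * xc[i];
    }
    const double m = s / G;
    double v = s2 / G - m * m;
    if (v < 0) v = 0;
    const double sd = std::sqrt(v);
    mu[w] = m;
    ok[w] = sd > 1e-12;
    inv_sd[w] = ok[w] ? 1.0 / sd : 0.0;
    zero_z[w] = -m * inv_sd[w];
  }

  // CSR over genes: non-zero entries of scorable columns
  std::vector<int> row_ptr(G + 1, 0);
  for (int w = 0; w < W; ++w) {
    if (!ok[w]) continue;
    const double* xc = &x(0, w);
    for (int i = 0; i < G; ++i)
      if (xc[i] != 0) ++row_ptr[i + 1];
  }
  for (int i = 0; i < G; ++i) row_ptr[i + 1] += row_ptr[i];
  const int nnz = row_ptr[G];
  std::vector<int> col_idx(nnz);
  std::vector<double> zval(nnz);
  {
    std::vector<int> fill(row_ptr.begin(), row_ptr.end() - 1);
    for (int w = 0; w < W; ++w) {
      if (!ok[w]) continue;
      const double* xc = &x(0, w);
      for (int i = 0; i < G; ++i) {
        if (xc[i] != 0) {
          const int at = fill[i]++;
          col_idx[at] = w;
          zval[at] = (xc[i] - mu[w]) * inv_sd[w];
        }
      }
    }
  }

  NumericMatrix out(W, B);
  const double inv_sqrt_g = 1.0 / std::sqrt((double)G);
  std::vector<double> S(W), M(W);
  std::vector<int> last(W), first(W);
  for (int b = 0; b < B; ++b) {
    std::fill(S.begin(), S.end(), 0.0);
    std::fill(M.begin(), M.end(), R_NegInf);
    std::fill(last.begin(), last.end(), 0);
    std::fill(first.begin(), first.end(), 0);
    const int* ord = &orders(0, b);
    for (int i = 1; i <= G; ++i) {
      const int g = ord[i - 1] - 1;
      for (int e = row_ptr[g]; e < row_ptr[g + 1]; ++e) {
        const int w = col_idx[e];
        S[w] += zero_z[w] * (i - 1 - last[w]) + zval[e];
        if (S[w] > M[w]) M[w] = S[w];
        if (first[w] == 0) first[w] = i;
        last[w] = i;
      }
    }
    for (int w = 0; w < W; ++w) {
      if (!ok[w]) {
        out(w, b) = NA_REAL;
        continue;
      }
      double m = M[w];
      // a leading run of zeros peaks at position 1
      if (first[w] > 1 && zero_z[w] > m) m = zero_z[w];
      out(w, b) = m * inv_sqrt_g;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
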