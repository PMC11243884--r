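#include <Rcpp.h>
using namespace Rcpp;

// Periodized (circular) analysis/synthesis filter-bank steps.
//
// Signals are the columns of a matrix; N (number of rows) must be even.
// Analysis convention:  a[k] = sum_m lo[m] * x[(2k + M/2 - m) mod N]
// Synthesis convention: x[n] = sum_j rlo[j] * ua[(n - j + M/2 - 1) mod N] + ...
// with ua/ud the zero-stuffed upsampled subbands. The pairing reconstructs
// exactly for any biorthogonal quadruple satisfying the perfect-reconstruction
// conditions, including filters longer than the signal (full circular wrap).

static inline int imod(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// [[Rcpp::export]]
List pdwt_analysis(NumericMatrix x, NumericVector lo, NumericVector hi) {
  const int N = x.nrow(), K = x.ncol(), M = lo.size();
  if (N % 2 != 0) stop("signal length must be even");
  if (hi.size() != M) stop("filters must have equal length");
  const int H = N / 2;
  NumericMatrix a(H, K), d(H, K);
  std::vector<int> idx(static_cast<size_t>(H) * M);
  for (int k = 0; k < H; ++k)
    for (int m = 0; m < M; ++m)
      idx[static_cast<size_t>(k) * M + m] = imod(2 * k + M / 2 - m, N);
  for (int j = 0; j < K; ++j) {
    const double* xc = &x(0, j);
    for (int k = 0; k < H; ++k) {
      double sa = 0.0, sd = 0.0;
      const int* row = &idx[static_cast<size_t>(k) * M];
      for (int m = 0; m < M; ++m) {
        const double v = xc[row[m]];
        sa += lo[m] * v;
        sd += hi[m] * v;
      }
      a(k, j) = sa;
      d(k, j) = sd;
    }
  }
  return List::create(_["a"] = a, _["d"] = d);
}

// [[Rcpp::export]]
NumericMatrix pdwt_synthesis(NumericMatrix a, NumericMatrix d,
                             NumericVector rlo, NumericVector rhi) {
  const int H = a.nrow(), K = a.ncol(), M = rlo.size();
  if (d.nrow() != H || d.ncol() != K) stop("subband shapes differ");
  if (rhi.size() != M) stop("filters must have equal length");
  const int N = 2 * H;
  const int t = M / 2 - 1;
  NumericMatrix x(N, K);
  // scatter form: ua[(n - j + t) mod N] contributes when n = (2k + j - t) mod N
  std::vector<int> idx(static_cast<size_t>(H) * M);
  for (int k = 0; k < H; ++k)
    for (int m = 0; m < M; ++m)
      idx[static_cast<size_t>(k) * M + m] = imod(2 * k + m - t, N);
  for (int j = 0; j < K; ++j) {
    double* xc = &x(0, j);
    for (int k = 0; k < H; ++k) {
      const double va = a(k, j), vd = d(k, j);
      const int* row = &idx[static_cast<size_t>(k) * M];
      for (int m = 0; m < M; ++m)
        xc[row[m]] += rlo[m] * va + rhi[m] * vd;
    }
  }
  return x;
}
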