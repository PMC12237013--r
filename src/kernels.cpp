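// Sparse message-passing kernels: gather/scatter primitives shared by all
// layer forward and backward passes. Indices are 1-based (R convention).
#include <Rcpp.h>
using namespace Rcpp;

// out[idx[e], ] += vals[e, ]
// [[Rcpp::export]]
NumericMatrix cpp_scatter_add(const NumericMatrix& vals,
                              const IntegerVector& idx, int n) {
  int e = vals.nrow(), d = vals.ncol();
  NumericMatrix out(n, d);
  const int* id = idx.begin();
  const double* v = vals.begin();
  double* o = out.begin();
  for (int j = 0; j < d; ++j, v += e, o += n)
    for (int i = 0; i < e; ++i) o[id[i] - 1] += v[i];
  return out;
}

// out[idx[e]] += vals[e]
// [[Rcpp::export]]
NumericVector cpp_scatter_add_vec(const NumericVector& vals,
                                  const IntegerVector& idx, int n) {
  NumericVector out(n);
  const int* id = idx.begin();
  const double* v = vals.begin();
  double* o = out.begin();
  int e = vals.size();
  for (int i = 0; i < e; ++i) o[id[i] - 1] += v[i];
  return out;
}

// out[dst[e], ] += w[e] * H[src[e], ]  (w may be NULL for unit weights)
// [[Rcpp::export]]
NumericMatrix cpp_gather_scatter(const NumericMatrix& H,
                                 const IntegerVector& src,
                                 const IntegerVector& dst,
                                 Nullable<NumericVector> w, int n) {
  int e = src.size(), d = H.ncol(), rows = H.nrow();
  NumericMatrix out(n, d);
  const int* ps = src.begin();
  const int* pd = dst.begin();
  const double* h = H.begin();
  double* o = out.begin();
  if (w.isNotNull()) {
    NumericVector wv(w.get());
    const double* pw = wv.begin();
    for (int j = 0; j < d; ++j, h += rows, o += n)
      for (int i = 0; i < e; ++i) o[pd[i] - 1] += pw[i] * h[ps[i] - 1];
  } else {
    for (int j = 0; j < d; ++j, h += rows, o += n)
      for (int i = 0; i < e; ++i) o[pd[i] - 1] += h[ps[i] - 1];
  }
  return out;
}

// per-edge inner product: out[e] = sum_k A(dst[e], k) * B(src[e], k)
// [[Rcpp::export]]
NumericVector cpp_edge_dot(const NumericMatrix& A, const NumericMatrix& B,
                           const IntegerVector& src,
                           const IntegerVector& dst) {
  int e = src.size(), d = A.ncol(), ra = A.nrow(), rb = B.nrow();
  NumericVector out(e);
  const int* ps = src.begin();
  const int* pd = dst.begin();
  const double* a = A.begin();
  const double* b = B.begin();
  double* o = out.begin();
  for (int j = 0; j < d; ++j, a += ra, b += rb)
    for (int i = 0; i < e; ++i) o[i] += a[pd[i] - 1] * b[ps[i] - 1];
  return out;
}

// per-edge row sum: out(e, ) = A(src[e], ) + B(dst[e], )
// [[Rcpp::export]]
NumericMatrix cpp_edge_pair_sum(const NumericMatrix& A,
                                const NumericMatrix& B,
                                const IntegerVector& src,
                                const IntegerVector& dst) {
  int e = src.size(), d = A.ncol(), ra = A.nrow(), rb = B.nrow();
  NumericMatrix out(e, d);
  const int* ps = src.begin();
  const int* pd = dst.begin();
  const double* a = A.begin();
  const double* b = B.begin();
  double* o = out.begin();
  for (int j = 0; j < d; ++j, a += ra, b += rb, o += e)
    for (int i = 0; i < e; ++i) o[i] = a[ps[i] - 1] + b[pd[i] - 1];
  return out;
}

// per-group maximum of e over idx groups (for stable edge softmax)
// [[Rcpp::export]]
NumericVector cpp_group_max(const NumericVector& e, const IntegerVector& idx,
                            int n) {
  NumericVector out(n, R_NegInf);
  const int* id = idx.begin();
  const double* v = e.begin();
  double* o = out.begin();
  int m = e.size();
  for (int i = 0; i < m; ++i) {
    int g = id[i] - 1;
    if (v[i] > o[g]) o[g] = v[i];
  }
  return out;
}
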