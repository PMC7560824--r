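#include <Rcpp.h>
using namespace Rcpp;

// Regularized Kaczmarz sweeps on the real row-stacked system.
//
// Solves min ||A c - u||^2 + lambda ||c||^2 by row action on the augmented
// system [A; sqrt(lambda) I], keeping the auxiliary residual variable v for
// the regularization rows implicitly (one scalar per data row). With enough
// sweeps and lambda > 0 this converges to the Tikhonov solution; an optional
// projection c >= 0 is applied after every sweep.
//
// A: rows x n, u: rows, order: 0-based row visiting order.
// [[Rcpp::export(name = ".kaczmarz_core")]]
List kaczmarz_core(const NumericMatrix& A,
                   const NumericVector& u,
                   double lambda,
                   int sweeps,
                   bool nonneg,
                   const IntegerVector& order,
                   NumericVector c0,
                   bool track_residual) {
  const int m = A.nrow();
  const int n = A.ncol();
  if (u.size() != m) stop("length(u) must equal nrow(A)");
  NumericVector c = clone(c0);
  if (c.size() != n) stop("length(c0) must equal ncol(A)");
  std::vector<double> v(m, 0.0);
  const double sql = std::sqrt(lambda);

  // cache squared row norms
  std::vector<double> rn2(m);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) { double a = A(i, j); s += a * a; }
    rn2[i] = s;
  }

  NumericVector resid(track_residual ? sweeps : 0);
  for (int sw = 0; sw < sweeps; ++sw) {
    for (int oi = 0; oi < order.size(); ++oi) {
      const int i = order[oi];
      if (i < 0 || i >= m) stop("row order index out of range");
      const double denom = rn2[i] + lambda;
      if (denom <= 0.0) continue;
      double dot = 0.0;
      for (int j = 0; j < n; ++j) dot += A(i, j) * c[j];
      const double alpha = (u[i] - dot - sql * v[i]) / denom;
      for (int j = 0; j < n; ++j) c[j] += alpha * A(i, j);
      v[i] += alpha * sql;
    }
    if (nonneg) {
      for (int j = 0; j < n; ++j) if (c[j] < 0.0) c[j] = 0.0;
    }
    if (track_residual) {
      // residual of the lifted consistent system A c + sqrt(lambda) v = u
      double s = 0.0;
      for (int i = 0; i < m; ++i) {
        double dot = 0.0;
        for (int j = 0; j < n; ++j) dot += A(i, j) * c[j];
        const double r = u[i] - dot - sql * v[i];
        s += r * r;
      }
      resid[sw] = std::sqrt(s);
    }
  }
  return List::create(_["c"] = c, _["v"] = NumericVector(v.begin(), v.end()),
                      _["residual"] = resid);
}
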