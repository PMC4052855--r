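#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Per-group complex phase sums A_g(q) = sum_{i in g} w_i exp(2*pi*i q.x_i).
// q in 1/angstrom (rows of Q), positions in angstrom (rows of X), w a
// per-atom real weight (occupancy / ionization state), group a 1-based
// group index per atom (e.g. element index). Returns an m x G complex
// matrix; the structure factor is F(q) = sum_g f_g(q) * A_g(q).
// [[Rcpp::export]]
ComplexMatrix phase_sums(const NumericMatrix& Q, const NumericMatrix& X,
                         const NumericVector& w, const IntegerVector& group,
                         int n_groups) {
  const int m = Q.nrow(), n = X.nrow();
  if (X.ncol() != 3 || Q.ncol() != 3)
    stop("Q and X must have 3 columns");
  if (w.size() != n || group.size() != n)
    stop("w and group must have one entry per atom");
  ComplexMatrix out(m, n_groups);
  std::vector<std::complex<double> > acc(n_groups);
  const double twopi = 2.0 * M_PI;
  for (int j = 0; j < m; ++j) {
    std::fill(acc.begin(), acc.end(), std::complex<double>(0.0, 0.0));
    const double qx = Q(j, 0), qy = Q(j, 1), qz = Q(j, 2);
    for (int i = 0; i < n; ++i) {
      if (w[i] == 0.0) continue;
      const double ph = twopi * (qx * X(i, 0) + qy * X(i, 1) + qz * X(i, 2));
      acc[group[i] - 1] += w[i] * std::complex<double>(std::cos(ph), std::sin(ph));
    }
    for (int g = 0; g < n_groups; ++g) {
      out(j, g).r = acc[g].real();
      out(j, g).i = acc[g].imag();
    }
  }
  return out;
}
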