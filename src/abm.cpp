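#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Full-memory Adams-Bashforth-Moulton predictor-corrector for the Caputo
// initial-value problem D^alpha y = f(t, y), y(0) = y0, 0 < alpha <= 1,
// on the uniform grid t_n = n h, n = 0..N.
//
// Predictor:  y^P_{n+1} = y0 + (1/Gamma(alpha)) sum_j b_{j,n+1} f_j
//   with b_{j,n+1} = (h^alpha/alpha) [ (n+1-j)^alpha - (n-j)^alpha ].
// Corrector:  y_{n+1} = y0 + (h^alpha/Gamma(alpha+2))
//                       [ f(t_{n+1}, y^P_{n+1}) + sum_j a_{j,n+1} f_j ]
//   with a_{0,n+1} = n^{alpha+1} - (n-alpha)(n+1)^alpha and, for 1<=j<=n,
//   a_{j,n+1} = (n-j+2)^{alpha+1} + (n-j)^{alpha+1} - 2 (n-j+1)^{alpha+1}.
//
// The weights depend only on the lag n-j, so the stabilized differences are
// tabulated once (avoiding cancellation at large n) and each step reduces to
// two dot products over the contiguous f-history. The corrector is
// re-applied corrector_iterations times, each pass re-evaluating f at the
// current iterate; the stored history value is f at the accepted point.
//
// [[Rcpp::export]]
List abm_solve_cpp(Function f, NumericVector y0, double alpha, double h,
                   int N, int corrector_iterations) {
  const int dim = y0.size();
  NumericMatrix Y(N + 1, dim);

  // weight tables indexed by lag
  std::vector<double> pa(N + 2), pa1(N + 3), wb(N + 1), wa(N + 1);
  for (int m = 0; m <= N + 1; ++m) pa[m] = std::pow((double)m, alpha);
  for (int m = 0; m <= N + 2; ++m) pa1[m] = std::pow((double)m, alpha + 1.0);
  for (int l = 0; l <= N; ++l) {
    wb[l] = pa[l + 1] - pa[l];
    wa[l] = pa1[l + 2] + pa1[l] - 2.0 * pa1[l + 1];
  }
  const double ha = std::pow(h, alpha);
  const double cp = ha / R::gammafn(alpha + 1.0);  // predictor prefactor
  const double cc = ha / R::gammafn(alpha + 2.0);  // corrector prefactor

  std::vector<double> Fh((size_t)(N + 1) * dim);   // f history, row j contiguous
  std::vector<double> sp(dim), sc(dim);

  for (int kk = 0; kk < dim; ++kk) Y(0, kk) = y0[kk];
  NumericVector f0 = f(0.0, y0);
  if (f0.size() != dim)
    stop("rhs returned a vector of length %d, expected %d", (int)f0.size(), dim);
  for (int kk = 0; kk < dim; ++kk) Fh[kk] = f0[kk];

  bool ok = true;
  int done = 0;

  for (int n = 0; n < N && ok; ++n) {
    const double tn1 = (n + 1) * h;

    // history convolutions over j = 1..n (lag = n - j)
    for (int kk = 0; kk < dim; ++kk) { sp[kk] = 0.0; sc[kk] = 0.0; }
    {
      const double* fj = Fh.data() + dim;
      for (int j = 1; j <= n; ++j, fj += dim) {
        const int lag = n - j;
        const double b = wb[lag], a = wa[lag];
        for (int kk = 0; kk < dim; ++kk) {
          sp[kk] += b * fj[kk];
          sc[kk] += a * fj[kk];
        }
      }
    }
    // j = 0 terms (corrector j=0 weight is not a pure lag function)
    const double b0 = wb[n];
    const double a0 = pa1[n] - (n - alpha) * pa[n + 1];
    for (int kk = 0; kk < dim; ++kk) {
      sp[kk] += b0 * Fh[kk];
      sc[kk] += a0 * Fh[kk];
    }

    NumericVector ycur(dim);
    for (int kk = 0; kk < dim; ++kk) ycur[kk] = y0[kk] + cp * sp[kk];

    // never hand a non-finite state to the user's rhs
    for (int kk = 0; kk < dim; ++kk)
      if (!std::isfinite(ycur[kk])) { ok = false; }
    for (int it = 0; it < corrector_iterations && ok; ++it) {
      NumericVector fc = f(tn1, ycur);
      for (int kk = 0; kk < dim; ++kk) {
        ycur[kk] = y0[kk] + cc * (fc[kk] + sc[kk]);
        if (!std::isfinite(ycur[kk])) ok = false;
      }
    }
    if (!ok) break;

    NumericVector fnew = f(tn1, ycur);
    double* frow = Fh.data() + (size_t)(n + 1) * dim;
    for (int kk = 0; kk < dim; ++kk) {
      Y(n + 1, kk) = ycur[kk];
      frow[kk] = fnew[kk];
      if (!std::isfinite(fnew[kk])) ok = false;
    }
    if (ok) done = n + 1;
    if ((n & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["states"] = Y, _["ok"] = ok, _["steps_done"] = done);
}
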