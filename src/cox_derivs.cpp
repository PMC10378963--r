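#include <Rcpp.h>
using namespace Rcpp;

// Breslow partial-likelihood derivatives on time-sorted data.
//
// Rows of Xs are sorted by decreasing survival time, so risk sets are
// leading row blocks. pos_end[i] (1-based) is the last index of row i's
// tie group; ev_ends / d_ev list the tie-group ends that contain events
// and their event counts, in increasing index order. The Hessian
// accumulates the weighted Gram matrix S2 incrementally as rows enter
// the risk set, giving O(n p^2) total work.
//
// [[Rcpp::export]]
List cox_derivs_cpp(const NumericMatrix& Xs, const NumericVector& eta,
                    const NumericVector& d, const IntegerVector& pos_end,
                    const IntegerVector& ev_ends,
                    const NumericVector& d_ev, bool want_hessian) {
  const int n = Xs.nrow(), p = Xs.ncol();
  double shift = R_NegInf;
  for (int i = 0; i < n; ++i) shift = std::max(shift, eta[i]);

  std::vector<double> w(n), cumw(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    w[i] = std::exp(eta[i] - shift);
    acc += w[i];
    cumw[i] = acc;
  }
  // cumX[j] column-wise running sums of w * x
  NumericMatrix cumX(n, p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      s += w[i] * Xs(i, j);
      cumX(i, j) = s;
    }
  }

  double ll = 0.0;
  NumericVector g(p);
  for (int i = 0; i < n; ++i) {
    if (d[i] > 0) {
      const int e = pos_end[i] - 1;
      ll += d[i] * (eta[i] - shift - std::log(cumw[e]));
      for (int j = 0; j < p; ++j)
        g[j] += d[i] * (Xs(i, j) - cumX(e, j) / cumw[e]);
    }
  }

  NumericMatrix H(p, p);
  if (want_hessian) {
    // row-major copy so the rank-1 updates walk contiguous memory
    std::vector<double> Xt(static_cast<size_t>(n) * p);
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < n; ++i) Xt[static_cast<size_t>(i) * p + j] = Xs(i, j);
    std::vector<double> S2(p * p, 0.0), u(p);
    int prev = 0;
    for (int m = 0; m < ev_ends.size(); ++m) {
      const int e = ev_ends[m];          // 1-based group end
      for (int i = prev; i < e; ++i) {   // rows entering the risk set
        const double wi = w[i];
        const double* xi = &Xt[static_cast<size_t>(i) * p];
        for (int j = 0; j < p; ++j) {
          const double wx = wi * xi[j];
          double* s2j = &S2[static_cast<size_t>(j) * p];
          for (int k = j; k < p; ++k) s2j[k] += wx * xi[k];
        }
      }
      prev = e;
      const double S0 = cumw[e - 1], dm = d_ev[m];
      for (int j = 0; j < p; ++j) u[j] = cumX(e - 1, j) / S0;
      for (int j = 0; j < p; ++j)
        for (int k = j; k < p; ++k)
          H(j, k) += dm * (S2[j * p + k] / S0 - u[j] * u[k]);
    }
    for (int j = 0; j < p; ++j)
      for (int k = 0; k < j; ++k) H(j, k) = H(k, j);
  }
  return List::create(_["ll"] = ll, _["g"] = g, _["H"] = H);
}
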