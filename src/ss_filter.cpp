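#include <Rcpp.h>
using namespace Rcpp;

// Discrete state-space recursion x_{t+1} = Ad x_t + Bd u_t, y_t = C x_t.
// Hot loop of the stochastic simulator; everything else stays in R.
// [[Rcpp::export]]
NumericVector ss_filter(NumericMatrix Ad, NumericVector Bd,
                        NumericVector C, NumericVector u) {
  const int n = u.size();
  const int d = Ad.nrow();
  if (Ad.ncol() != d || Bd.size() != d || C.size() != d)
    stop("inconsistent state dimensions");
  std::vector<double> x(d, 0.0), xn(d, 0.0);
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double acc = 0.0;
    for (int i = 0; i < d; ++i) acc += C[i] * x[i];
    y[t] = acc;
    for (int i = 0; i < d; ++i) {
      double s = Bd[i] * u[t];
      for (int j = 0; j < d; ++j) s += Ad(i, j) * x[j];
      xn[i] = s;
    }
    std::swap(x, xn);
  }
  return y;
}
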