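#include <Rcpp.h>
using namespace Rcpp;

// BTEM objective: derivative entropy of the (smoothed) basis combination
// plus negativity and target-dominance penalties. Hot path of the simplex
// search, so evaluated in C++.
//
// V: n x z basis matrix; t: z coefficients; idx0: 0-based channel indices
// of the target window. The estimate is rescaled so its maximum inside
// the target window is 1 before smoothing and scoring.
// [[Rcpp::export]]
double btem_objective_cpp(const NumericMatrix& V, const NumericVector& t,
                          const IntegerVector& idx0, double gamma,
                          double deadband, double cap, int smooth) {
  const int n = V.nrow(), z = V.ncol();
  std::vector<double> x(n, 0.0);
  for (int j = 0; j < z; ++j) {
    const double tj = t[j];
    if (tj == 0.0) continue;
    const double* col = &V(0, j);
    for (int i = 0; i < n; ++i) x[i] += col[i] * tj;
  }
  double m = R_NegInf;
  for (int k = 0; k < idx0.size(); ++k) {
    const double v = x[idx0[k]];
    if (v > m) m = v;
  }
  if (m <= 0.0) return 1e9 * (1.0 - m);
  for (int i = 0; i < n; ++i) x[i] /= m;

  // centred boxcar smoothing, dropping edge channels where it cannot fit
  std::vector<double> xs;
  if (smooth > 1) {
    const int h = smooth / 2;
    xs.resize(n - 2 * h);
    double acc = 0.0;
    for (int i = 0; i < smooth - 1; ++i) acc += x[i];
    for (int i = h; i < n - h; ++i) {
      acc += x[i + h];
      xs[i - h] = acc / smooth;
      acc -= x[i - h];
    }
  } else {
    xs = x;
  }

  const int ns = (int) xs.size();
  double tot = 0.0;
  for (int i = 1; i < ns; ++i) tot += std::fabs(xs[i] - xs[i - 1]);
  double h_ent = 0.0;
  if (tot > 0.0) {
    for (int i = 1; i < ns; ++i) {
      const double p = std::fabs(xs[i] - xs[i - 1]) / tot;
      if (p > 0.0) h_ent -= p * std::log(p);
    }
  }
  double pen = 0.0;
  for (int i = 0; i < ns; ++i) {
    const double lo = xs[i] + deadband;
    if (lo < 0.0) pen += lo * lo;
    const double hi = xs[i] - cap;
    if (hi > 0.0) pen += hi * hi;
  }
  return h_ent + gamma * pen;
}
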