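#include <Rcpp.h>
using namespace Rcpp;

// Single-pass direct-form-I IIR filter, zero initial conditions.
static void iir_pass(const std::vector<double>& b, const std::vector<double>& a,
                     std::vector<double>& x) {
  const int n = x.size(), nb = b.size(), na = a.size();
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nb && j <= i; ++j) acc += b[j] * x[i - j];
    for (int j = 1; j < na && j <= i; ++j) acc -= a[j] * y[i - j];
    y[i] = acc;
  }
  x.swap(y);
}

// Zero-phase (forward-backward) IIR filtering of each column of X, with
// odd-reflection padding of `pad` samples at both ends to absorb transients.
// [[Rcpp::export(name = ".filtfilt_mat")]]
NumericMatrix filtfilt_mat(NumericVector b, NumericVector a,
                           NumericMatrix X, int pad) {
  const int n = X.nrow(), k = X.ncol();
  if (pad > n - 1) pad = n - 1;
  if (pad < 0) pad = 0;
  const int m = n + 2 * pad;
  std::vector<double> bb(b.begin(), b.end()), aa(a.begin(), a.end());
  NumericMatrix out(n, k);
  std::vector<double> w(m);
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < pad; ++i) w[i] = 2.0 * X(0, j) - X(pad - i, j);
    for (int i = 0; i < n; ++i) w[pad + i] = X(i, j);
    for (int i = 0; i < pad; ++i) w[pad + n + i] = 2.0 * X(n - 1, j) - X(n - 2 - i, j);
    iir_pass(bb, aa, w);
    std::reverse(w.begin(), w.end());
    iir_pass(bb, aa, w);
    std::reverse(w.begin(), w.end());
    for (int i = 0; i < n; ++i) out(i, j) = w[pad + i];
  }
  return out;
}
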