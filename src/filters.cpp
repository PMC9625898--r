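#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Cascade of identical complex one-pole sections y[n] = x[n] + a * y[n-1].
// Used for the all-pole gammatone realisation (real part of the output) and
// for the complex modulation resonators (magnitude of the output).
// [[Rcpp::export]]
ComplexVector cpp_complex_cascade(NumericVector x, double a_re, double a_im,
                                  int order) {
  int n = x.size();
  std::complex<double> a(a_re, a_im);
  std::vector< std::complex<double> > y(n);
  for (int i = 0; i < n; ++i) y[i] = std::complex<double>(x[i], 0.0);
  for (int s = 0; s < order; ++s) {
    std::complex<double> prev(0.0, 0.0);
    for (int i = 0; i < n; ++i) {
      prev = y[i] + a * prev;
      y[i] = prev;
    }
  }
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i].r = y[i].real();
    out[i].i = y[i].imag();
  }
  return out;
}

// Divisive adaptation loops with smooth overshoot limiting.  Each loop
// divides the signal by a lowpass-filtered copy of its own output; the
// cascade compresses stationary inputs almost logarithmically while passing
// fast fluctuations nearly linearly.  `a1` are the per-loop lowpass
// coefficients exp(-1/(tau*fs)); `state0` the stationary divisors for the
// minimum input; `limit` > 1 engages the sigmoidal overshoot limiter.
// [[Rcpp::export]]
NumericVector cpp_adaptation_loops(NumericVector x, NumericVector a1,
                                   NumericVector state0, double limit,
                                   double minlvl) {
  int n = x.size(), nloops = a1.size();
  NumericVector out(n);
  std::vector<double> state(state0.begin(), state0.end());
  std::vector<double> maxv(nloops), fac(nloops), expf(nloops), off(nloops);
  bool limited = limit > 1.0;
  if (limited) {
    for (int k = 0; k < nloops; ++k) {
      maxv[k] = (1.0 - state0[k] * state0[k]) * limit - 1.0;
      fac[k]  = maxv[k] * 2.0;
      expf[k] = -2.0 / maxv[k];
      off[k]  = maxv[k] - 1.0;
    }
  }
  for (int i = 0; i < n; ++i) {
    double tmp = x[i];
    if (tmp < minlvl) tmp = minlvl;
    for (int k = 0; k < nloops; ++k) {
      tmp /= state[k];
      if (limited && tmp > 1.0)
        tmp = fac[k] / (1.0 + std::exp(expf[k] * (tmp - 1.0))) - off[k];
      state[k] = a1[k] * state[k] + (1.0 - a1[k]) * tmp;
    }
    out[i] = tmp;
  }
  return out;
}

// Direct-form II transposed IIR filter (single channel), matching
// signal::filter(b, a, x) but avoiding per-call object overhead in the
// per-channel loops of the chain runner.
// [[Rcpp::export]]
NumericVector cpp_iir(NumericVector b, NumericVector a, NumericVector x) {
  int n = x.size(), nb = b.size(), na = a.size();
  int nw = std::max(nb, na) - 1;
  std::vector<double> w(nw, 0.0), bb(nb), aa(na);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double yn = bb[0] * x[i] + (nw > 0 ? w[0] : 0.0);
    for (int k = 0; k < nw - 1; ++k) {
      double bk = (k + 1 < nb) ? bb[k + 1] : 0.0;
      double ak = (k + 1 < na) ? aa[k + 1] : 0.0;
      w[k] = bk * x[i] + w[k + 1] - ak * yn;
    }
    if (nw > 0) {
      double bk = (nw < nb) ? bb[nw] : 0.0;
      double ak = (nw < na) ? aa[nw] : 0.0;
      w[nw - 1] = bk * x[i] - ak * yn;
    }
    y[i] = yn;
  }
  return y;
}
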