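#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Narrowband delay-sum-integrate kernel.
//
// Z:     decimated complex baseband, time x channels
// shift: per (voxel, channel) integer delay in decimated samples
// phase: per (voxel, channel) complex carrier rotation exp(i*2*pi*f0*tau)
// w0,w1: integration window (0-based, half-open) in decimated samples
//
// Returns per-voxel mean |sum_c phase * Z(t + shift, c)|^2 over the window.
// Samples shifted past the end of the record contribute zero.
// [[Rcpp::export]]
NumericVector beamform_nb_kernel(ComplexMatrix Z, IntegerMatrix shift,
                                 ComplexMatrix phase, int w0, int w1) {
  const int T = Z.nrow(), C = Z.ncol(), V = shift.nrow();
  if (phase.nrow() != V || phase.ncol() != C || shift.ncol() != C)
    stop("shift/phase dimensions do not match");
  if (w1 <= w0) stop("empty integration window");
  const int W = w1 - w0;
  NumericVector out(V);
  const Rcomplex* zp = Z.begin();
  const Rcomplex* pp = phase.begin();
  const int* sp = shift.begin();
  std::vector<double> re(W), im(W);
  for (int v = 0; v < V; ++v) {
    std::fill(re.begin(), re.end(), 0.0);
    std::fill(im.begin(), im.end(), 0.0);
    for (int c = 0; c < C; ++c) {
      const int s = sp[v + (size_t)V * c];
      const Rcomplex p = pp[v + (size_t)V * c];
      const Rcomplex* zc = zp + (size_t)T * c;
      int t0 = w0 + s, t1 = w1 + s;  // source index range in Z
      if (t0 < 0) t0 = 0;
      if (t1 > T) t1 = T;
      for (int t = t0; t < t1; ++t) {
        const int k = t - s - w0;  // window-relative output index
        re[k] += p.r * zc[t].r - p.i * zc[t].i;
        im[k] += p.r * zc[t].i + p.i * zc[t].r;
      }
    }
    double acc = 0.0;
    for (int k = 0; k < W; ++k) acc += re[k] * re[k] + im[k] * im[k];
    out[v] = acc / W;
  }
  return out;
}
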