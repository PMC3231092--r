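#include <Rcpp.h>
using namespace Rcpp;

// 2-D cross-correlation with replicate (edge-clamp) border padding.
// The kernel is applied in correlation orientation (no flip); callers that
// want true convolution rotate the kernel by 180 degrees first.
// [[Rcpp::export]]
NumericMatrix xcorr2_replicate(NumericMatrix img, NumericMatrix kern) {
  const int M = img.nrow(), N = img.ncol();
  const int kr = kern.nrow(), kc = kern.ncol();
  if (kr > M || kc > N)
    stop("kernel (%d x %d) larger than image (%d x %d)", kr, kc, M, N);
  if (kr % 2 == 0 || kc % 2 == 0)
    stop("kernel dimensions must be odd");
  const int ar = kr / 2, ac = kc / 2;  // anchor offsets
  NumericMatrix out(M, N);
  for (int x = 0; x < N; ++x) {
    for (int y = 0; y < M; ++y) {
      double acc = 0.0;
      for (int j = 0; j < kc; ++j) {
        int cx = x + j - ac;
        if (cx < 0) cx = 0; else if (cx >= N) cx = N - 1;
        for (int i = 0; i < kr; ++i) {
          int cy = y + i - ar;
          if (cy < 0) cy = 0; else if (cy >= M) cy = M - 1;
          acc += kern(i, j) * img(cy, cx);
        }
      }
      out(y, x) = acc;
    }
  }
  return out;
}
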