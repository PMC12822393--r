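#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sliding-window speckle contrast K = sd/mean (population sd) per pixel and
// frame, via per-frame integral images. Frames are stored (row, col, frame).
// K is defined only where the full window fits; elsewhere NA. A window whose
// mean is <= 0 yields NA (undefined contrast), never an exception.
template <typename T>
static void contrast_frames(const T* x, double* out,
                            const int nr, const int nc, const int nt,
                            const int w) {
  const int half = w / 2;
  const double n = (double)(w * w);
  const R_xlen_t fsz = (R_xlen_t)nr * nc;
  std::vector<double> S((size_t)(nr + 1) * (nc + 1));
  std::vector<double> S2((size_t)(nr + 1) * (nc + 1));
  const int sr = nr + 1;

  for (int t = 0; t < nt; ++t) {
    const T* f = x + (R_xlen_t)t * fsz;
    double* o = out + (R_xlen_t)t * fsz;
    // integral images, S[(c+1)*sr + (r+1)] = sum over rows<=r, cols<=c
    for (int r = 0; r <= nr; ++r) { S[r] = 0.0; S2[r] = 0.0; }
    for (int c = 0; c < nc; ++c) {
      double run = 0.0, run2 = 0.0;
      const size_t off = (size_t)(c + 1) * sr, offp = (size_t)c * sr;
      S[off] = 0.0; S2[off] = 0.0;
      for (int r = 0; r < nr; ++r) {
        const double v = (double)f[(R_xlen_t)c * nr + r];
        run += v; run2 += v * v;
        S[off + r + 1] = S[offp + r + 1] + run;
        S2[off + r + 1] = S2[offp + r + 1] + run2;
      }
    }
    for (int c = 0; c < nc; ++c) {
      double* oc = o + (R_xlen_t)c * nr;
      if (c < half || c >= nc - half) {
        for (int r = 0; r < nr; ++r) oc[r] = NA_REAL;
        continue;
      }
      const size_t c0 = (size_t)(c - half) * sr, c1 = (size_t)(c + half + 1) * sr;
      for (int r = 0; r < nr; ++r) {
        if (r < half || r >= nr - half) { oc[r] = NA_REAL; continue; }
        const int r0 = r - half, r1 = r + half + 1;
        const double sum = S[c1 + r1] - S[c1 + r0] - S[c0 + r1] + S[c0 + r0];
        const double mean = sum / n;
        if (!(mean > 0.0)) { oc[r] = NA_REAL; continue; }
        const double sum2 = S2[c1 + r1] - S2[c1 + r0] - S2[c0 + r1] + S2[c0 + r0];
        double v = sum2 / n - mean * mean;
        if (v < 0.0) v = 0.0;  // guard rounding on near-constant windows
        oc[r] = std::sqrt(v) / mean;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector spatial_contrast_cpp(SEXP frames, int window) {
  IntegerVector dims;
  if (Rf_isArray(frames)) dims = as<IntegerVector>(Rf_getAttrib(frames, R_DimSymbol));
  if (dims.size() != 3) stop("frames must be a 3-D (row, col, frame) array");
  const int nr = dims[0], nc = dims[1], nt = dims[2];
  if (window < 3 || window % 2 == 0) stop("window must be an odd integer >= 3");
  if (window > nr || window > nc) stop("window exceeds image dimensions");
  NumericVector out((R_xlen_t)nr * nc * nt);
  out.attr("dim") = dims;
  if (TYPEOF(frames) == INTSXP) {
    contrast_frames<int>(INTEGER(frames), REAL(out), nr, nc, nt, window);
  } else if (TYPEOF(frames) == REALSXP) {
    contrast_frames<double>(REAL(frames), REAL(out), nr, nc, nt, window);
  } else {
    stop("frames must be integer or double");
  }
  return out;
}

// Linear-interpolation resampling of a (row-major over time) frame block onto
// phase positions, accumulating into `acc`. Used by the representative-cycle
// ensemble average to avoid materialising per-cycle resampled stacks.
// `frames` is (npx, nt) with columns = frames of one cycle (in order);
// `pos` gives fractional column positions (0-based) for each phase sample.
// [[Rcpp::export]]
void accumulate_cycle_cpp(NumericMatrix frames, NumericVector pos,
                          NumericMatrix acc) {
  const int npx = frames.nrow(), nt = frames.ncol();
  const int np = pos.size();
  if (acc.nrow() != npx || acc.ncol() != np)
    stop("accumulator shape mismatch");
  for (int j = 0; j < np; ++j) {
    double p = pos[j];
    if (p < 0) p = 0;
    if (p > nt - 1) p = nt - 1;
    int i0 = (int)std::floor(p);
    if (i0 > nt - 2) i0 = nt - 2;
    if (i0 < 0) i0 = 0;
    const double wgt = p - i0;
    const double* a = &frames(0, i0);
    const double* b = &frames(0, i0 + 1);
    double* o = &acc(0, j);
    for (int i = 0; i < npx; ++i) o[i] += a[i] * (1.0 - wgt) + b[i] * wgt;
  }
}
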