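#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Direct evaluation of the per-row lagged product moment
//   r(k,t) = 1/(N-t) * sum_{n=1}^{N-t} x(k,n) x(k,n+t),  t = 0..max_lag,
// optionally removing each row's mean first. Rows are copied to contiguous
// scratch so the inner dot products stream through cache.
// [[Rcpp::export]]
NumericMatrix autocorr_rows(NumericMatrix x, int max_lag, bool demean) {
  const int K = x.nrow(), N = x.ncol();
  if (max_lag < 0 || max_lag >= N) stop("max_lag must be in [0, N-1]");
  NumericMatrix out(K, max_lag + 1);
  std::vector<double> row(N);
  for (int k = 0; k < K; ++k) {
    double mu = 0.0;
    for (int n = 0; n < N; ++n) { row[n] = x(k, n); mu += row[n]; }
    if (demean) {
      mu /= N;
      for (int n = 0; n < N; ++n) row[n] -= mu;
    }
    for (int t = 0; t <= max_lag; ++t) {
      const int m = N - t;
      const double *p = row.data();
      const double *q = row.data() + t;
      double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
      int n = 0;
      for (; n + 4 <= m; n += 4) {
        s0 += p[n] * q[n];
        s1 += p[n + 1] * q[n + 1];
        s2 += p[n + 2] * q[n + 2];
        s3 += p[n + 3] * q[n + 3];
      }
      double s = (s0 + s1) + (s2 + s3);
      for (; n < m; ++n) s += p[n] * q[n];
      out(k, t) = s / m;
    }
  }
  return out;
}

// Windowed analysis frames packed in pairs: column j holds frame 2j as the
// real part and frame 2j+1 as the imaginary part (zero frame if unpaired),
// so one complex FFT transforms two real frames.
// [[Rcpp::export]]
ComplexMatrix pack_frames(NumericVector x, IntegerVector starts0,
                          NumericVector w) {
  const int L = w.size();
  const int nb = starts0.size();
  const int np = (nb + 1) / 2;
  ComplexMatrix out(L, np);
  for (int j = 0; j < np; ++j) {
    const int f1 = starts0[2 * j];
    const bool has2 = 2 * j + 1 < nb;
    const int f2 = has2 ? starts0[2 * j + 1] : 0;
    for (int k = 0; k < L; ++k) {
      Rcomplex z;
      z.r = x[f1 + k] * w[k];
      z.i = has2 ? x[f2 + k] * w[k] : 0.0;
      out[j * L + k] = z;  // column-major fill
    }
  }
  return out;
}

static inline void unpack_pair(const Rcomplex &z, const Rcomplex &zr,
                               double &x1r, double &x1i,
                               double &x2r, double &x2i) {
  // X1 = (Z + conj(Zrev))/2, X2 = (Z - conj(Zrev))/(2i)
  x1r = 0.5 * (z.r + zr.r);
  x1i = 0.5 * (z.i - zr.i);
  x2r = 0.5 * (z.i + zr.i);
  x2i = -0.5 * (z.r - zr.r);
}

// Per-frame power spectra (non-negative bins 0..B-1) recovered from packed
// transforms: column 2j from the real frame of pair j, 2j+1 from the
// imaginary one.
// [[Rcpp::export]]
NumericMatrix packed_power(ComplexMatrix Z, int B) {
  const int L = Z.nrow(), np = Z.ncol();
  NumericMatrix P(B, 2 * np);
  for (int j = 0; j < np; ++j) {
    for (int k = 0; k < B; ++k) {
      const int kr = (k == 0) ? 0 : L - k;
      double x1r, x1i, x2r, x2i;
      unpack_pair(Z(k, j), Z(kr, j), x1r, x1i, x2r, x2i);
      P(k, 2 * j) = x1r * x1r + x1i * x1i;
      P(k, 2 * j + 1) = x2r * x2r + x2i * x2i;
    }
  }
  return P;
}

// Apply per-bin gains (half-spectrum matrix G, one column per frame) to the
// packed spectra and repack: Y = G1.*X1 + i * (G2.*X2). The result is again
// one complex column per frame pair, ready for a single inverse FFT.
// [[Rcpp::export]]
ComplexMatrix packed_gain(ComplexMatrix Z, NumericMatrix G) {
  const int L = Z.nrow(), np = Z.ncol();
  const int B = G.nrow();
  if (G.ncol() < 2 * np) stop("gain matrix has too few columns");
  ComplexMatrix Y(L, np);
  for (int j = 0; j < np; ++j) {
    for (int k = 0; k < L; ++k) {
      const int kr = (k == 0) ? 0 : L - k;
      const int kk = (k < B) ? k : L - k;  // mirror bin for the gain
      double x1r, x1i, x2r, x2i;
      unpack_pair(Z(k, j), Z(kr, j), x1r, x1i, x2r, x2i);
      const double g1 = G(kk, 2 * j), g2 = G(kk, 2 * j + 1);
      Rcomplex y;
      y.r = g1 * x1r - g2 * x2i;
      y.i = g1 * x1i + g2 * x2r;
      Y[j * L + k] = y;
    }
  }
  return Y;
}

// Overlap-add of inverse-transformed packed frames into `out` (modified in
// place): frame 2j is the real part of column j, frame 2j+1 the imaginary
// part.
// [[Rcpp::export]]
void ola_add(NumericVector out, ComplexMatrix Yt, IntegerVector starts0) {
  const int L = Yt.nrow();
  const int nb = starts0.size();
  for (int f = 0; f < nb; ++f) {
    const int j = f / 2;
    const bool re = (f % 2 == 0);
    const int s = starts0[f];
    for (int k = 0; k < L; ++k) {
      out[s + k] += re ? Yt(k, j).r : Yt(k, j).i;
    }
  }
}

// Per-column sample quantile (type 7) over the first n_used rows of a
// matrix. Columns are contiguous in memory, so selection needs no
// transposed copy; used for the per-bin noise tracker, whose history ring
// is stored frames x bins.
// [[Rcpp::export]]
NumericVector col_quantiles(NumericMatrix x, int n_used, double p) {
  const int nr = x.nrow(), nc = x.ncol();
  if (n_used < 1 || n_used > nr) stop("invalid n_used");
  if (p < 0.0 || p > 1.0) stop("p must be in [0, 1]");
  NumericVector out(nc);
  std::vector<double> buf(n_used);
  const double h = p * (n_used - 1);
  const int lo = (int)h;
  const double g = h - lo;
  for (int j = 0; j < nc; ++j) {
    const double *col = &x(0, j);
    std::copy(col, col + n_used, buf.begin());
    std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
    double v_lo = buf[lo];
    double v_hi = v_lo;
    if (g > 0.0 && lo < n_used - 1) {
      v_hi = *std::min_element(buf.begin() + lo + 1, buf.end());
    }
    out[j] = (1.0 - g) * v_lo + g * v_hi;
  }
  return out;
}

// Floored Wiener gain for one tracker segment (columns s0..s1, 0-based,
// inclusive), written into G in place.
// [[Rcpp::export]]
void segment_gain(NumericMatrix P, NumericMatrix G, int s0, int s1,
                  NumericVector lambda, double a, double gmin) {
  const int B = P.nrow();
  for (int j = s0; j <= s1; ++j) {
    for (int k = 0; k < B; ++k) {
      double p = P(k, j);
      if (p < 1e-300) p = 1e-300;
      const double g = 1.0 - a * lambda[k] / p;
      G(k, j) = (g > gmin) ? g : gmin;
    }
  }
}

// Append power-spectrum columns s0..s1 (0-based, stepping by `stride`) of P
// as rows of the circular history ring (frames x bins). The quantile later
// taken over the ring is order-free, so old rows are simply overwritten.
// Returns the updated (write position, fill count).
// [[Rcpp::export]]
IntegerVector ring_push(NumericMatrix ring, NumericMatrix P, int s0, int s1,
                        int pos, int fill, int stride) {
  const int cap = ring.nrow();
  const int B = P.nrow();
  for (int j = s0; j <= s1; j += stride) {
    for (int k = 0; k < B; ++k) ring(pos, k) = P(k, j);
    pos = (pos + 1) % cap;
    if (fill < cap) ++fill;
  }
  return IntegerVector::create(pos, fill);
}

// First positive local peak of each row within columns [lo, hi] (0-based),
// normalized by that row's r0; -Inf when the row has no peak.
// [[Rcpp::export]]
NumericVector first_peak_amp(NumericMatrix R, NumericVector r0,
                             int lo, int hi) {
  const int K = R.nrow(), nl = R.ncol();
  if (lo < 1) lo = 1;
  if (hi > nl - 2) hi = nl - 2;
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    double amp = R_NegInf;
    for (int j = lo; j <= hi; ++j) {
      const double v = R(k, j);
      if (v > 0 && v > R(k, j - 1) && v >= R(k, j + 1)) {
        amp = v / r0[k];
        break;
      }
    }
    out[k] = amp;
  }
  return out;
}

// Direct-form-II-transposed IIR filter y = filter(b, a, x); a[0] must be 1
// (or is normalized out). Avoids the time-series bookkeeping of R-level
// filtering on whole-night vectors.
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  if (na < 1 || a[0] == 0) stop("invalid denominator");
  const int ns = std::max(nb, na) - 1;
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0), z(ns + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int s = 0; s < ns; ++s) {
      z[s] = bb[s + 1] * xi + z[s + 1] - aa[s + 1] * yi;
    }
    y[i] = yi;
  }
  return y;
}

// Frame-wise mean square of a signal: frames of length L every H samples.
// [[Rcpp::export]]
NumericVector frame_msq(NumericVector x, int L, int H) {
  const int n = x.size();
  if (n < L) return NumericVector(0);
  const int m = (n - L) / H + 1;
  NumericVector out(m);
  for (int f = 0; f < m; ++f) {
    const double *p = &x[0] + (size_t)f * H;
    double s = 0.0;
    for (int k = 0; k < L; ++k) s += p[k] * p[k];
    out[f] = s / L;
  }
  return out;
}
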