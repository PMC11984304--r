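#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int lowest_bit_index(unsigned m) {
  int i = 0;
  while (!(m & 1u)) { m >>= 1; ++i; }
  return i;
}

// Zero-lag cross-cumulant image on an order-fold oversampled virtual lattice.
//
// X            : T x P matrix of mean-subtracted pixel time series; pixel (row r,
//                col c) of the H x W camera frame is column c*H + r (0-based).
// order        : cumulant order n in 2..6.
// part_nblocks : number of blocks of each set partition of {1..n} with all
//                blocks of size >= 2 (singleton blocks vanish on centred data).
// block_masks  : flattened bitmasks (bit i = series i) of the blocks, in
//                partition order.
// part_weights : (-1)^(b-1) (b-1)! per partition.
//
// The virtual pixel at fine-lattice point (R, C) (lattice (0,0) at camera pixel
// centre (0,0), spacing 1/n camera px) combines the n-pixel multiset with
// k = C mod n x-coordinates at base+1 and n-k at base (same in y), paired
// ascending-ascending: the variance-minimising combination with the
// lexicographic tie-break. Fine points whose combination would need a pixel
// beyond the camera frame are returned as NA (filled during flattening).
// [[Rcpp::export]]
NumericVector cpp_cross_cumulant_values(const NumericMatrix& X, int H, int W,
                                        int order,
                                        const IntegerVector& part_nblocks,
                                        const IntegerVector& block_masks,
                                        const NumericVector& part_weights) {
  const int T = X.nrow();
  const int n = order;
  const int FH = H * n, FW = W * n;
  const int nmask = 1 << n;
  NumericVector out((R_xlen_t)FH * (R_xlen_t)FW, NA_REAL);
  std::vector<double> mom(nmask), prod(nmask);
  std::vector<const double*> s(n);
  std::vector<int> lowbit(nmask, 0);
  for (int m = 1; m < nmask; ++m) lowbit[m] = lowest_bit_index((unsigned)m);
  int ys[6], xs[6];
  const int npart = part_nblocks.size();

  for (int C = 0; C < FW; ++C) {
    const int bx = C / n, kx = C % n;
    if (kx > 0 && bx + 1 >= W) continue;
    for (int R = 0; R < FH; ++R) {
      const int by = R / n, ky = R % n;
      if (ky > 0 && by + 1 >= H) continue;
      for (int i = 0; i < n; ++i) {
        ys[i] = by + ((i < n - ky) ? 0 : 1);
        xs[i] = bx + ((i < n - kx) ? 0 : 1);
      }
      for (int i = 0; i < n; ++i) s[i] = &X(0, xs[i] * H + ys[i]);
      std::fill(mom.begin(), mom.end(), 0.0);
      for (int t = 0; t < T; ++t) {
        prod[0] = 1.0;
        for (int m = 1; m < nmask; ++m)
          prod[m] = prod[m & (m - 1)] * s[lowbit[m]][t];
        for (int m = 3; m < nmask; ++m) mom[m] += prod[m];
      }
      const double invT = 1.0 / (double)T;
      for (int m = 3; m < nmask; ++m) mom[m] *= invT;
      double val = 0.0;
      int pos = 0;
      for (int p = 0; p < npart; ++p) {
        double term = part_weights[p];
        const int nb = part_nblocks[p];
        for (int b = 0; b < nb; ++b) term *= mom[block_masks[pos++]];
        val += term;
      }
      out[(R_xlen_t)C * FH + R] = val;
    }
  }
  return out;
}

// Leave-one-frame-out auto-cumulant images for jackknife SNR estimation.
// Returns per-pixel running sum and sum of squares of the N leave-one-out
// cumulant values, computed from updatable raw power sums (no recomputation).
// order in 1..4; X is the raw (uncentred) T x P movie matrix.
// [[Rcpp::export]]
List cpp_jackknife_moments(const NumericMatrix& X, int order) {
  const int T = X.nrow(), P = X.ncol();
  NumericVector sumI(P, 0.0), sumI2(P, 0.0);
  std::vector<double> xc(T);
  const double Np = (double)(T - 1);
  for (int p = 0; p < P; ++p) {
    const double* x = &X(0, p);
    // centre the series first: cumulants of order >= 2 are shift-invariant
    // and the order-1 jackknife variance is too, while centring avoids the
    // catastrophic cancellation of large camera offsets in the power sums
    double mu0 = 0;
    for (int t = 0; t < T; ++t) mu0 += x[t];
    mu0 /= T;
    double S1 = 0, S2 = 0, S3 = 0, S4 = 0;
    for (int t = 0; t < T; ++t) {
      const double v = x[t] - mu0, v2 = v * v;
      xc[t] = v;
      S1 += v; S2 += v2;
      if (order >= 3) S3 += v2 * v;
      if (order >= 4) S4 += v2 * v2;
    }
    double acc = 0, acc2 = 0;
    for (int t = 0; t < T; ++t) {
      const double v = xc[t], v2 = v * v;
      const double mu = (S1 - v) / Np;
      double I;
      if (order == 1) {
        I = mu;
      } else {
        const double m2 = (S2 - v2) / Np - mu * mu;
        if (order == 2) {
          I = m2;
        } else {
          const double e3 = (S3 - v2 * v) / Np;
          const double e2 = (S2 - v2) / Np;
          const double m3 = e3 - 3.0 * mu * e2 + 2.0 * mu * mu * mu;
          if (order == 3) {
            I = m3;
          } else {
            const double e4 = (S4 - v2 * v2) / Np;
            const double m4 = e4 - 4.0 * mu * e3 + 6.0 * mu * mu * e2 -
                              3.0 * mu * mu * mu * mu;
            I = m4 - 3.0 * m2 * m2;
          }
        }
      }
      acc += I; acc2 += I * I;
    }
    sumI[p] = acc; sumI2[p] = acc2;
  }
  return List::create(_["sum"] = sumI, _["sumsq"] = sumI2, _["n"] = T);
}
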