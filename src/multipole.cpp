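// Real solid-harmonic interaction and translation matrices.
// Same math as the R-level documentation: scaled regular/irregular complex
// solids by recursion, then the unitary complex-to-real transform applied
// blockwise (two nonzeros per row, so O(size) per block).
#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;
typedef std::complex<double> cplx;

static inline int lmi(int l, int m) { return l * l + l + m; } // 0-based

// scaled regular solids Rt_l^m = r^l P_l^m e^{im phi}/(l+m)!
static void regular_cplx(int L, const double *r, std::vector<cplx> &out) {
  out.assign((L + 1) * (L + 1), cplx(0.0, 0.0));
  const double x = r[0], y = r[1], z = r[2];
  const double rr = x * x + y * y + z * z;
  out[0] = cplx(1.0, 0.0);
  if (L == 0) return;
  const cplx xy(x, y);
  cplx diag(1.0, 0.0);
  for (int l = 1; l <= L; ++l) {
    diag *= -xy / (2.0 * l);
    out[lmi(l, l)] = diag;
    out[lmi(l, -l)] = ((l % 2) ? -1.0 : 1.0) * std::conj(diag);
    for (int m = 0; m < l; ++m) {
      cplx r1 = out[lmi(l - 1, m)];
      cplx r2 = (m <= l - 2) ? out[lmi(l - 2, m)] : cplx(0.0, 0.0);
      cplx v = ((2.0 * l - 1.0) * z * r1 - rr * r2) / double((l + m) * (l - m));
      out[lmi(l, m)] = v;
      if (m > 0) out[lmi(l, -m)] = ((m % 2) ? -1.0 : 1.0) * std::conj(v);
    }
  }
}

// scaled irregular solids It_l^m = (l-m)! P_l^m e^{im phi} / r^{l+1}
static void irregular_cplx(int L, const double *r, std::vector<cplx> &out) {
  out.assign((L + 1) * (L + 1), cplx(0.0, 0.0));
  const double x = r[0], y = r[1], z = r[2];
  const double rr = x * x + y * y + z * z;
  out[0] = cplx(1.0 / std::sqrt(rr), 0.0);
  if (L == 0) return;
  const cplx xy(x, y);
  cplx diag = out[0];
  for (int l = 1; l <= L; ++l) {
    diag *= -(2.0 * l - 1.0) * xy / rr;
    out[lmi(l, l)] = diag;
    out[lmi(l, -l)] = ((l % 2) ? -1.0 : 1.0) * std::conj(diag);
    for (int m = 0; m < l; ++m) {
      cplx i1 = out[lmi(l - 1, m)];
      cplx i2 = (m <= l - 2) ? out[lmi(l - 2, m)] : cplx(0.0, 0.0);
      cplx v = ((2.0 * l - 1.0) * z * i1 -
                double((l - 1) * (l - 1) - m * m) * i2) / rr;
      out[lmi(l, m)] = v;
      if (m > 0) out[lmi(l, -m)] = ((m % 2) ? -1.0 : 1.0) * std::conj(v);
    }
  }
}

// in-place two-sided complex-to-real transform of block (2l1+1) x (2l2+1):
// computes Re(conj(U_l1) blk U_l2^dagger)
static void real_block_cpp(std::vector<cplx> &blk, int l1, int l2,
                           std::vector<double> &out) {
  const int n1 = 2 * l1 + 1, n2 = 2 * l2 + 1;
  const double is2 = 1.0 / std::sqrt(2.0);
  for (int m = 1; m <= l1; ++m) {
    const double s = (m % 2) ? -1.0 : 1.0;
    for (int j = 0; j < n2; ++j) {
      cplx top = blk[(size_t)(l1 + m) * n2 + j];
      cplx bot = blk[(size_t)(l1 - m) * n2 + j];
      blk[(size_t)(l1 + m) * n2 + j] = (s * top + bot) * is2;
      blk[(size_t)(l1 - m) * n2 + j] = cplx(0.0, 1.0) * (s * top - bot) * is2;
    }
  }
  for (int m = 1; m <= l2; ++m) {
    const double s = (m % 2) ? -1.0 : 1.0;
    for (int i = 0; i < n1; ++i) {
      cplx rgt = blk[(size_t)i * n2 + (l2 + m)];
      cplx lft = blk[(size_t)i * n2 + (l2 - m)];
      blk[(size_t)i * n2 + (l2 + m)] = (s * rgt + lft) * is2;
      blk[(size_t)i * n2 + (l2 - m)] = cplx(0.0, 1.0) * (s * rgt - lft) * is2;
    }
  }
  out.resize((size_t)n1 * n2);
  for (size_t k = 0; k < out.size(); ++k) out[k] = blk[k].real();
}

// [[Rcpp::export(name = ".interaction_tensor_cpp")]]
NumericMatrix interaction_tensor_cpp(NumericVector P, NumericVector Q,
                                     int L, int Lp) {
  double R[3] = {Q[0] - P[0], Q[1] - P[1], Q[2] - P[2]};
  std::vector<cplx> irr;
  irregular_cplx(L + Lp, R, irr);
  for (size_t k = 0; k < irr.size(); ++k) irr[k] = std::conj(irr[k]);
  const int n1 = (L + 1) * (L + 1), n2 = (Lp + 1) * (Lp + 1);
  NumericMatrix out(n1, n2);
  std::vector<cplx> blk;
  std::vector<double> rb;
  for (int l1 = 0; l1 <= L; ++l1) {
    for (int l2 = 0; l2 <= Lp; ++l2) {
      const int b1 = 2 * l1 + 1, b2 = 2 * l2 + 1;
      const double sgn = (l2 % 2) ? -1.0 : 1.0;
      blk.assign((size_t)b1 * b2, cplx(0.0, 0.0));
      for (int m1 = -l1; m1 <= l1; ++m1)
        for (int m2 = -l2; m2 <= l2; ++m2)
          blk[(size_t)(m1 + l1) * b2 + (m2 + l2)] =
            sgn * irr[lmi(l1 + l2, m1 + m2)];
      real_block_cpp(blk, l1, l2, rb);
      const int r0 = lmi(l1, -l1), c0 = lmi(l2, -l2);
      for (int i = 0; i < b1; ++i)
        for (int j = 0; j < b2; ++j)
          out(r0 + i, c0 + j) = rb[(size_t)i * b2 + j];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".translation_matrix_cpp")]]
NumericMatrix translation_matrix_cpp(NumericVector from, NumericVector to,
                                     int Lfrom, int Lto) {
  const int n1 = (Lto + 1) * (Lto + 1), n2 = (Lfrom + 1) * (Lfrom + 1);
  NumericMatrix out(n1, n2);
  double d[3] = {from[0] - to[0], from[1] - to[1], from[2] - to[2]};
  if (d[0] == 0.0 && d[1] == 0.0 && d[2] == 0.0) {
    const int k = std::min(n1, n2);
    for (int i = 0; i < k; ++i) out(i, i) = 1.0;
    return out;
  }
  std::vector<cplx> reg;
  regular_cplx(Lto, d, reg);
  std::vector<cplx> blk;
  std::vector<double> rb;
  for (int l = 0; l <= Lto; ++l) {
    const int lpmax = std::min(l, Lfrom);
    for (int lp = 0; lp <= lpmax; ++lp) {
      const int b1 = 2 * l + 1, b2 = 2 * lp + 1;
      blk.assign((size_t)b1 * b2, cplx(0.0, 0.0));
      for (int m = -l; m <= l; ++m)
        for (int mp = -lp; mp <= lp; ++mp) {
          const int dm = m - mp;
          if (std::abs(dm) <= l - lp)
            blk[(size_t)(m + l) * b2 + (mp + lp)] = reg[lmi(l - lp, dm)];
        }
      real_block_cpp(blk, l, lp, rb);
      // U (not conj(U)) on the left: negate the sine rows (m < 0)
      const int r0 = lmi(l, -l), c0 = lmi(lp, -lp);
      for (int i = 0; i < b1; ++i) {
        const double f = (i < l) ? -1.0 : 1.0;
        for (int j = 0; j < b2; ++j)
          out(r0 + i, c0 + j) = f * rb[(size_t)i * b2 + j];
      }
    }
  }
  return out;
}
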