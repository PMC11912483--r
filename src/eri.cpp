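// McMurchie-Davidson hot kernels: Boys function, Hermite Coulomb R-tables and
// the primitive-pair repulsion contractions. Conventions mirror the R-level
// documentation exactly: the R-table holds R^0_{tuv}(p, PQ) seeded by
// (-2p)^n F_n(p|PQ|^2); the 2 pi^{5/2}/(p q sqrt(p+q)) prefactor and the
// (-1)^{t+u+v} ket parity are applied during contraction.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void boys_fill(int m, double T, double *F) {
  if (T < 1e-14) {
    for (int j = 0; j <= m; ++j) F[j] = 1.0 / (2.0 * j + 1.0);
    return;
  }
  double eT = std::exp(-T);
  if (T <= 45.0) {
    double term = 1.0 / (2.0 * m + 1.0), s = term;
    for (int k = 1; k <= 500; ++k) {
      term *= 2.0 * T / (2.0 * m + 2.0 * k + 1.0);
      s += term;
      if (term < s * 1e-17) break;
    }
    F[m] = eT * s;
    for (int j = m; j >= 1; --j) F[j - 1] = (2.0 * T * F[j] + eT) / (2.0 * j - 1.0);
  } else {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    for (int j = 0; j < m; ++j) F[j + 1] = ((2.0 * j + 1.0) * F[j] - eT) / (2.0 * T);
  }
}

// R^0_{tuv} for t+u+v <= nmax, flat index t*(nmax+1)^2 + u*(nmax+1) + v
static void rtable(int nmax, double p, const double *PQ, std::vector<double> &out) {
  const int d = nmax + 1, dd = d * d;
  double T = p * (PQ[0] * PQ[0] + PQ[1] * PQ[1] + PQ[2] * PQ[2]);
  std::vector<double> F(nmax + 1);
  boys_fill(nmax, T, F.data());
  std::vector<double> prev(d * dd, 0.0), cur(d * dd, 0.0);
  for (int n = nmax; n >= 0; --n) {
    std::fill(cur.begin(), cur.end(), 0.0);
    cur[0] = std::pow(-2.0 * p, n) * F[n];
    const int smax = nmax - n;
    for (int s = 1; s <= smax; ++s) {
      for (int t = s; t >= 0; --t) {
        for (int u = s - t; u >= 0; --u) {
          const int v = s - t - u;
          double val;
          if (t > 0) {
            val = PQ[0] * prev[(t - 1) * dd + u * d + v];
            if (t > 1) val += (t - 1) * prev[(t - 2) * dd + u * d + v];
          } else if (u > 0) {
            val = PQ[1] * prev[(u - 1) * d + v];
            if (u > 1) val += (u - 1) * prev[(u - 2) * d + v];
          } else {
            val = PQ[2] * prev[v - 1];
            if (v > 1) val += (v - 1) * prev[v - 2];
          }
          cur[t * dd + u * d + v] = val;
        }
      }
    }
    std::swap(prev, cur);
  }
  out = prev;
}

// Hermite index triples for total order <= n, in the package's fixed order
static void hermite_idx(int n, std::vector<int> &t, std::vector<int> &u,
                        std::vector<int> &v) {
  t.clear(); u.clear(); v.clear();
  for (int s = 0; s <= n; ++s) {
    for (int tt = s; tt >= 0; --tt) {
      for (int uu = s - tt; uu >= 0; --uu) {
        t.push_back(tt); u.push_back(uu); v.push_back(s - tt - uu);
      }
    }
  }
}

// [[Rcpp::export(name = ".eri_dist_cpp")]]
NumericMatrix eri_dist_cpp(List prims1, int nfun1, List prims2, int nfun2) {
  NumericMatrix out(nfun1, nfun2);
  const int n1 = prims1.size(), n2 = prims2.size();
  std::vector<double> Rt;
  std::vector<int> t1, u1, v1, t2, u2, v2;
  for (int b = 0; b < n2; ++b) {
    List pr2 = prims2[b];
    const double p2 = as<double>(pr2["p"]);
    NumericVector P2 = pr2["P"];
    const int l2 = as<int>(pr2["lsum"]);
    NumericMatrix E2 = pr2["E"];
    hermite_idx(l2, t2, u2, v2);
    const int nh2 = (int)t2.size();
    // fold ket parity into a copy of E2
    std::vector<double> E2s((size_t)nh2 * nfun2);
    for (int j = 0; j < nfun2; ++j)
      for (int i = 0; i < nh2; ++i) {
        const double sgn = ((t2[i] + u2[i] + v2[i]) % 2) ? -1.0 : 1.0;
        E2s[(size_t)j * nh2 + i] = sgn * E2(i, j);
      }
    for (int a = 0; a < n1; ++a) {
      List pr1 = prims1[a];
      const double p1 = as<double>(pr1["p"]);
      NumericVector P1 = pr1["P"];
      const int l1 = as<int>(pr1["lsum"]);
      NumericMatrix E1 = pr1["E"];
      hermite_idx(l1, t1, u1, v1);
      const int nh1 = (int)t1.size();
      const int ntot = l1 + l2, d = ntot + 1, dd = d * d;
      const double xi = p1 * p2 / (p1 + p2);
      double PQ[3] = {P1[0] - P2[0], P1[1] - P2[1], P1[2] - P2[2]};
      rtable(ntot, xi, PQ, Rt);
      const double pref = 2.0 * std::pow(M_PI, 2.5) /
        (p1 * p2 * std::sqrt(p1 + p2));
      // tmp[i][j2] = sum_j R(i,j) E2s(j, j2)
      std::vector<double> tmp((size_t)nh1 * nfun2, 0.0);
      for (int i = 0; i < nh1; ++i) {
        const int ti = t1[i], ui = u1[i], vi = v1[i];
        for (int j = 0; j < nh2; ++j) {
          const double r = Rt[(ti + t2[j]) * dd + (ui + u2[j]) * d + (vi + v2[j])];
          if (r == 0.0) continue;
          for (int j2 = 0; j2 < nfun2; ++j2)
            tmp[(size_t)j2 * nh1 + i] += r * E2s[(size_t)j2 * nh2 + j];
        }
      }
      for (int j2 = 0; j2 < nfun2; ++j2)
        for (int j1 = 0; j1 < nfun1; ++j1) {
          double s = 0.0;
          for (int i = 0; i < nh1; ++i) s += E1(i, j1) * tmp[(size_t)j2 * nh1 + i];
          out(j1, j2) += pref * s;
        }
    }
  }
  return out;
}

// pref * Rmat %*% v2 between two Hermite primitive sets (no parity applied:
// the caller folds (-1)^{t+u+v} into v2). Used by the Split-RI-J Hermite path.
// [[Rcpp::export(name = ".rvec_contract_cpp")]]
NumericVector rvec_contract_cpp(double p1, NumericVector P1, int l1,
                                double p2, NumericVector P2, int l2,
                                NumericVector v2vec) {
  std::vector<int> t1, u1, v1, t2, u2, v2;
  hermite_idx(l1, t1, u1, v1);
  hermite_idx(l2, t2, u2, v2);
  const int nh1 = (int)t1.size(), nh2 = (int)t2.size();
  const int ntot = l1 + l2, d = ntot + 1, dd = d * d;
  const double xi = p1 * p2 / (p1 + p2);
  double PQ[3] = {P1[0] - P2[0], P1[1] - P2[1], P1[2] - P2[2]};
  std::vector<double> Rt;
  rtable(ntot, xi, PQ, Rt);
  const double pref = 2.0 * std::pow(M_PI, 2.5) / (p1 * p2 * std::sqrt(p1 + p2));
  NumericVector out(nh1);
  for (int i = 0; i < nh1; ++i) {
    double s = 0.0;
    for (int j = 0; j < nh2; ++j)
      s += Rt[(t1[i] + t2[j]) * dd + (u1[i] + u2[j]) * d + (v1[i] + v2[j])] * v2vec[j];
    out[i] = pref * s;
  }
  return out;
}
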