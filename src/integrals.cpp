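// Gaussian integral engine: McMurchie-Davidson scheme over contracted
// Cartesian Gaussians. Supports arbitrary angular momentum via the Hermite
// recursions; the shipped basis sets use only s and p shells.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double PI = 3.14159265358979323846;

// Boys function F_0..F_mmax at x, downward recursion from a convergent series
// (x small/moderate) or upward from the asymptotic closed form (x large).
void boys(int mmax, double x, std::vector<double> &F) {
  F.assign(mmax + 1, 0.0);
  if (x < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (x > 35.0) {
    F[0] = 0.5 * std::sqrt(PI / x);
    double ex = std::exp(-x);
    for (int m = 1; m <= mmax; ++m)
      F[m] = ((2.0 * m - 1.0) * F[m - 1] - ex) / (2.0 * x);
    return;
  }
  // series for F_mmax, then downward
  double term = 1.0 / (2.0 * mmax + 1.0);
  double sum = term;
  for (int i = 1; i < 200; ++i) {
    term *= 2.0 * x / (2.0 * mmax + 2.0 * i + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  double ex = std::exp(-x);
  F[mmax] = ex * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
}

// Hermite expansion coefficients E_t^{ij} for one Cartesian direction.
// et[(i,j,t)] laid out as a small 3-d table.
struct ETable {
  int imax, jmax, tmax;
  std::vector<double> v;
  double &at(int i, int j, int t) { return v[(i * (jmax + 1) + j) * (tmax + 1) + t]; }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * (tmax + 1) + t];
  }
};

ETable hermite_E(int imax, int jmax, double a, double b, double AB) {
  ETable E;
  E.imax = imax; E.jmax = jmax; E.tmax = imax + jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (E.tmax + 1), 0.0);
  double p = a + b, mu = a * b / p;
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  double XPA = -b * AB / p;   // P - A with AB = A - B
  double XPB = a * AB / p;    // P - B
  // build up i then j
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (i > 0) {
          val = E.get(i - 1, j, t - 1) / (2.0 * p)
              + XPA * E.get(i - 1, j, t)
              + (t + 1) * E.get(i - 1, j, t + 1);
        } else {
          val = E.get(i, j - 1, t - 1) / (2.0 * p)
              + XPB * E.get(i, j - 1, t)
              + (t + 1) * E.get(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  }
  return E;
}

// Hermite Coulomb integrals R_{tuv} via auxiliary R^n recursion.
struct RTable {
  int tmax, umax, vmax;
  std::vector<double> v;
  double &at(int t, int u, int w) { return v[(t * (umax + 1) + u) * (vmax + 1) + w]; }
};

RTable hermite_R(int tmax, int umax, int vmax, double p, double PCx, double PCy,
                 double PCz) {
  int nmax = tmax + umax + vmax;
  double T = p * (PCx * PCx + PCy * PCy + PCz * PCz);
  std::vector<double> F;
  boys(nmax, T, F);
  // R^n_{tuv} stored per n; iterate n downward
  auto idx = [&](int t, int u, int w) {
    return (t * (umax + 1) + u) * (vmax + 1) + w;
  };
  int sz = (tmax + 1) * (umax + 1) * (vmax + 1);
  std::vector<std::vector<double>> Rn(nmax + 1, std::vector<double>(sz, 0.0));
  for (int n = 0; n <= nmax; ++n) {
    double pref = std::pow(-2.0 * p, n);
    Rn[n][idx(0, 0, 0)] = pref * F[n];
  }
  // fill by total order
  for (int n = nmax - 1; n >= 0; --n) {
    for (int t = 0; t <= tmax; ++t)
      for (int u = 0; u <= umax; ++u)
        for (int w = 0; w <= vmax; ++w) {
          if (t + u + w == 0 || t + u + w > nmax - n) continue;
          double val;
          if (t > 0) {
            val = (t - 1 > 0 ? (t - 1) * Rn[n + 1][idx(t - 2, u, w)] : 0.0)
                + PCx * Rn[n + 1][idx(t - 1, u, w)];
          } else if (u > 0) {
            val = (u - 1 > 0 ? (u - 1) * Rn[n + 1][idx(t, u - 2, w)] : 0.0)
                + PCy * Rn[n + 1][idx(t, u - 1, w)];
          } else {
            val = (w - 1 > 0 ? (w - 1) * Rn[n + 1][idx(t, u, w - 2)] : 0.0)
                + PCz * Rn[n + 1][idx(t, u, w - 1)];
          }
          Rn[n][idx(t, u, w)] = val;
        }
  }
  RTable R;
  R.tmax = tmax; R.umax = umax; R.vmax = vmax;
  R.v = Rn[0];
  return R;
}

struct Prim {
  double exp_, coef;  // coef includes primitive normalization
};

struct BasisFn {                 // one contracted Cartesian AO
  int l[3];                      // Cartesian powers (lx, ly, lz)
  double O[3];                   // center (bohr)
  std::vector<Prim> prims;
};

double dfact(int n) {            // (2n-1)!! with n>=0 convention dfact(0)=1
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

// primitive normalization for Cartesian Gaussian with powers l, exponent a
double prim_norm(const int l[3], double a) {
  int L = l[0] + l[1] + l[2];
  double num = std::pow(2.0 * a / PI, 0.75) * std::pow(4.0 * a, 0.5 * L);
  double den = std::sqrt(dfact(l[0]) * dfact(l[1]) * dfact(l[2]));
  return num / den;
}

// per-dimension overlap building block s_{ij} = E_0^{ij}; full integral adds
// (pi/p)^{3/2}
double overlap_prim(const BasisFn &A, const BasisFn &B, double a, double b) {
  double p = a + b;
  double s = std::pow(PI / p, 1.5);
  for (int d = 0; d < 3; ++d) {
    ETable E = hermite_E(A.l[d], B.l[d], a, b, A.O[d] - B.O[d]);
    s *= E.get(A.l[d], B.l[d], 0);
  }
  return s;
}

// overlap with one Cartesian power on B shifted (for kinetic); j may be -2..+2
double overlap_prim_shift(const BasisFn &A, const BasisFn &B, double a, double b,
                          int dim, int shift) {
  int jb = B.l[dim] + shift;
  if (jb < 0) return 0.0;
  double p = a + b;
  double s = std::pow(PI / p, 1.5);
  for (int d = 0; d < 3; ++d) {
    int j = (d == dim) ? jb : B.l[d];
    ETable E = hermite_E(A.l[d], j, a, b, A.O[d] - B.O[d]);
    s *= E.get(A.l[d], j, 0);
  }
  return s;
}

double kinetic_prim(const BasisFn &A, const BasisFn &B, double a, double b) {
  double t = 0.0;
  for (int d = 0; d < 3; ++d) {
    int j = B.l[d];
    double term = -2.0 * b * b * overlap_prim_shift(A, B, a, b, d, +2)
                + b * (2.0 * j + 1.0) * overlap_prim(A, B, a, b)
                - 0.5 * j * (j - 1.0) * overlap_prim_shift(A, B, a, b, d, -2);
    t += term;
  }
  return t;
}

double nuclear_prim(const BasisFn &A, const BasisFn &B, double a, double b,
                    const std::vector<double> &Zs,
                    const std::vector<std::array<double, 3>> &Cs) {
  double p = a + b;
  double P[3];
  for (int d = 0; d < 3; ++d) P[d] = (a * A.O[d] + b * B.O[d]) / p;
  ETable Ex = hermite_E(A.l[0], B.l[0], a, b, A.O[0] - B.O[0]);
  ETable Ey = hermite_E(A.l[1], B.l[1], a, b, A.O[1] - B.O[1]);
  ETable Ez = hermite_E(A.l[2], B.l[2], a, b, A.O[2] - B.O[2]);
  int tmax = A.l[0] + B.l[0], umax = A.l[1] + B.l[1], vmax = A.l[2] + B.l[2];
  double v = 0.0;
  for (size_t c = 0; c < Zs.size(); ++c) {
    RTable R = hermite_R(tmax, umax, vmax, p, P[0] - Cs[c][0], P[1] - Cs[c][1],
                         P[2] - Cs[c][2]);
    double vc = 0.0;
    for (int t = 0; t <= tmax; ++t)
      for (int u = 0; u <= umax; ++u)
        for (int w = 0; w <= vmax; ++w)
          vc += Ex.get(A.l[0], B.l[0], t) * Ey.get(A.l[1], B.l[1], u) *
                Ez.get(A.l[2], B.l[2], w) * R.at(t, u, w);
    v += -Zs[c] * vc;
  }
  return v * 2.0 * PI / p;
}

BasisFn fn_from_list(const List &bf) {
  BasisFn f;
  IntegerVector l = bf["l"];
  NumericVector O = bf["origin"];
  NumericVector e = bf["exps"];
  NumericVector c = bf["coefs"];
  for (int d = 0; d < 3; ++d) { f.l[d] = l[d]; f.O[d] = O[d]; }
  for (int k = 0; k < e.size(); ++k) {
    Prim p;
    p.exp_ = e[k];
    p.coef = c[k] * prim_norm(f.l, e[k]);
    f.prims.push_back(p);
  }
  return f;
}

}  // namespace

// [[Rcpp::export]]
List one_electron_integrals(List basis, NumericVector charges,
                            NumericMatrix centers) {
  int n = basis.size();
  std::vector<BasisFn> fns;
  for (int i = 0; i < n; ++i) fns.push_back(fn_from_list(basis[i]));
  std::vector<double> Zs(charges.begin(), charges.end());
  std::vector<std::array<double, 3>> Cs(Zs.size());
  for (size_t c = 0; c < Zs.size(); ++c)
    for (int d = 0; d < 3; ++d) Cs[c][d] = centers(c, d);
  NumericMatrix S(n, n), T(n, n), V(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = 0.0, t = 0.0, v = 0.0;
      for (const Prim &pa : fns[i].prims)
        for (const Prim &pb : fns[j].prims) {
          double cc = pa.coef * pb.coef;
          s += cc * overlap_prim(fns[i], fns[j], pa.exp_, pb.exp_);
          t += cc * kinetic_prim(fns[i], fns[j], pa.exp_, pb.exp_);
          v += cc * nuclear_prim(fns[i], fns[j], pa.exp_, pb.exp_, Zs, Cs);
        }
      S(i, j) = S(j, i) = s;
      T(i, j) = T(j, i) = t;
      V(i, j) = V(j, i) = v;
    }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

namespace {

double eri_prim(const BasisFn &A, const BasisFn &B, const BasisFn &C,
                const BasisFn &D, double a, double b, double c, double d) {
  double p = a + b, q = c + d;
  double P[3], Q[3];
  for (int k = 0; k < 3; ++k) {
    P[k] = (a * A.O[k] + b * B.O[k]) / p;
    Q[k] = (c * C.O[k] + d * D.O[k]) / q;
  }
  double alpha = p * q / (p + q);
  ETable E1[3], E2[3];
  for (int k = 0; k < 3; ++k) {
    E1[k] = hermite_E(A.l[k], B.l[k], a, b, A.O[k] - B.O[k]);
    E2[k] = hermite_E(C.l[k], D.l[k], c, d, C.O[k] - D.O[k]);
  }
  int t1 = A.l[0] + B.l[0], u1 = A.l[1] + B.l[1], v1 = A.l[2] + B.l[2];
  int t2 = C.l[0] + D.l[0], u2 = C.l[1] + D.l[1], v2 = C.l[2] + D.l[2];
  RTable R = hermite_R(t1 + t2, u1 + u2, v1 + v2, alpha, P[0] - Q[0],
                       P[1] - Q[1], P[2] - Q[2]);
  double val = 0.0;
  for (int t = 0; t <= t1; ++t)
    for (int u = 0; u <= u1; ++u)
      for (int w = 0; w <= v1; ++w) {
        double e1 = E1[0].get(A.l[0], B.l[0], t) *
                    E1[1].get(A.l[1], B.l[1], u) *
                    E1[2].get(A.l[2], B.l[2], w);
        if (e1 == 0.0) continue;
        for (int tt = 0; tt <= t2; ++tt)
          for (int uu = 0; uu <= u2; ++uu)
            for (int ww = 0; ww <= v2; ++ww) {
              double e2 = E2[0].get(C.l[0], D.l[0], tt) *
                          E2[1].get(C.l[1], D.l[1], uu) *
                          E2[2].get(C.l[2], D.l[2], ww);
              if (e2 == 0.0) continue;
              double sgn = ((tt + uu + ww) % 2 == 0) ? 1.0 : -1.0;
              val += e1 * e2 * sgn * R.at(t + tt, u + uu, w + ww);
            }
      }
  return val * 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q));
}

}  // namespace

// [[Rcpp::export]]
NumericVector two_electron_integrals(List basis) {
  int n = basis.size();
  std::vector<BasisFn> fns;
  for (int i = 0; i < n; ++i) fns.push_back(fn_from_list(basis[i]));
  NumericVector eri((R_xlen_t)n * n * n * n);
  auto idx = [&](int i, int j, int k, int l) {
    return ((R_xlen_t)((i * n + j) * n + k)) * n + l;
  };
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j)
      for (int k = 0; k <= i; ++k)
        for (int l = 0; l <= ((k == i) ? j : k); ++l) {
          double v = 0.0;
          for (const Prim &pa : fns[i].prims)
            for (const Prim &pb : fns[j].prims)
              for (const Prim &pc : fns[k].prims)
                for (const Prim &pd : fns[l].prims)
                  v += pa.coef * pb.coef * pc.coef * pd.coef *
                       eri_prim(fns[i], fns[j], fns[k], fns[l], pa.exp_,
                                pb.exp_, pc.exp_, pd.exp_);
          eri[idx(i, j, k, l)] = v; eri[idx(j, i, k, l)] = v;
          eri[idx(i, j, l, k)] = v; eri[idx(j, i, l, k)] = v;
          eri[idx(k, l, i, j)] = v; eri[idx(l, k, i, j)] = v;
          eri[idx(k, l, j, i)] = v; eri[idx(l, k, j, i)] = v;
        }
  eri.attr("dim") = IntegerVector::create(n, n, n, n);
  return eri;
}
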