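// Integral kernels for the Gaussian lobe basis.
//
// Every basis function is a contraction of pure s-Gaussians (p shells are
// signed displaced lobes), so a single set of closed-form s-type expressions
// covers S, T, V, dipole and ERI evaluation.  The two-electron kernel follows
// the pair-table formulation: per-pair overlaps O_ab and product centers r_ab
// are precomputed, and every primitive ERI is
//   (g_a g_b | g_c g_d) = O_ab O_cd sqrt(P) 1F1(1/2, 3/2, -P d^2)
// with P = 1/(1/(a+b) + 1/(c+d)), d = |r_ab - r_cd| and
// 1F1(1/2,3/2,-x) = sqrt(pi) erf(sqrt(x)) / (2 sqrt(x)).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// Abramowitz-Stegun style rational erf approximation with the six printed
// coefficients; saturates to exactly 1 for x >= sat (default arg 4, where
// 1 - erf(4) ~ 1.5e-8).
static inline double erf_fast(double x, double sat) {
  if (x >= sat) return 1.0;
  const double c0 = 0.3275911;
  const double c1 = 0.254829592, c2 = -0.284496736, c3 = 1.421413741,
               c4 = -1.453152027, c5 = 1.061405429;
  double t = 1.0 / (1.0 + c0 * x);
  double p = t * (c1 + t * (c2 + t * (c3 + t * (c4 + t * c5))));
  return 1.0 - p * std::exp(-x * x);
}

// F0(x) = 1F1(1/2,3/2,-x); limit 1 at x = 0.  For small x the erf-based
// form loses relative precision (erf(sqrt(x))/sqrt(x) is 0/0-like and the
// rational erf approximation has no constraint on its slope at 0), which
// matters because sign-paired lobe primitives cancel heavily; the
// alternating series is exact to machine precision there.
static inline double f0_kernel(double x, double sat, bool exact) {
  if (x < 0.1) {
    return 1.0 + x * (-1.0 / 3.0 + x * (1.0 / 10.0 + x * (-1.0 / 42.0 +
               x * (1.0 / 216.0 + x * (-1.0 / 1320.0 + x / 9360.0)))));
  }
  double s = std::sqrt(x);
  double e = exact ? std::erf(s) : erf_fast(s, sat);
  return 0.5 * std::sqrt(PI) * e / s;
}

// [[Rcpp::export]]
NumericVector cpp_erf_approx(NumericVector x, double sat = 4.0) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (x[i] < 0) stop("erf_approx is defined for x >= 0 only");
    out[i] = erf_fast(x[i], sat);
  }
  return out;
}

struct BasisView {
  const int *off;     // nbf+1 offsets into primitive arrays (0-based)
  const double *A, *al, *x, *y, *z;
  int nbf;
};

static BasisView view_basis(IntegerVector off, NumericVector A, NumericVector al,
                            NumericVector x, NumericVector y, NumericVector z) {
  BasisView b;
  b.off = INTEGER(off); b.A = REAL(A); b.al = REAL(al);
  b.x = REAL(x); b.y = REAL(y); b.z = REAL(z);
  b.nbf = off.size() - 1;
  return b;
}

// One-electron integrals.  When Coulomb cut-off radii (Bohr) are supplied
// together with per-orbital parent-atom coordinates, each nuclear-attraction
// contribution is multiplied by the same smooth weight used for the ERIs,
// evaluated between the orbital-pair centre (mean of the two parent atoms)
// and the nucleus -- long-range electrostatics must be truncated
// consistently across e-e, e-n and n-n terms or neutral-system cancellation
// is lost.
// [[Rcpp::export]]
List cpp_one_electron(IntegerVector off, NumericVector A, NumericVector al,
                      NumericVector x, NumericVector y, NumericVector z,
                      NumericVector Zn, NumericMatrix nuc,
                      double sat = 4.0, bool exact_erf = false,
                      Nullable<NumericMatrix> atom_xyz = R_NilValue,
                      double rcl = -1.0, double rcu = -1.0) {
  BasisView b = view_basis(off, A, al, x, y, z);
  int n = b.nbf, nn = Zn.size();
  bool cut = rcu > 0 && atom_xyz.isNotNull();
  NumericMatrix ax;
  if (cut) ax = NumericMatrix(atom_xyz);
  double inv_span = (cut && rcu > rcl) ? 1.0 / (rcu - rcl) : 0.0;
  NumericMatrix S(n, n), T(n, n), V(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = 0, t = 0, v = 0;
      double pcx = 0, pcy = 0, pcz = 0;
      if (cut) {
        pcx = (ax(i, 0) + ax(j, 0)) / 2;
        pcy = (ax(i, 1) + ax(j, 1)) / 2;
        pcz = (ax(i, 2) + ax(j, 2)) / 2;
      }
      for (int a = b.off[i]; a < b.off[i + 1]; ++a) {
        for (int c = b.off[j]; c < b.off[j + 1]; ++c) {
          double g = b.al[a] + b.al[c];
          double xi = b.al[a] * b.al[c] / g;
          double dx = b.x[a] - b.x[c], dy = b.y[a] - b.y[c], dz = b.z[a] - b.z[c];
          double R2 = dx * dx + dy * dy + dz * dz;
          double pre = b.A[a] * b.A[c] * std::pow(PI / g, 1.5) * std::exp(-xi * R2);
          s += pre;
          t += pre * xi * (3.0 - 2.0 * xi * R2);
          // product Gaussian center
          double px = (b.al[a] * b.x[a] + b.al[c] * b.x[c]) / g;
          double py = (b.al[a] * b.y[a] + b.al[c] * b.y[c]) / g;
          double pz = (b.al[a] * b.z[a] + b.al[c] * b.z[c]) / g;
          double pre_v = b.A[a] * b.A[c] * 2.0 * PI / g * std::exp(-xi * R2);
          for (int k = 0; k < nn; ++k) {
            double cx = px - nuc(k, 0), cy = py - nuc(k, 1), cz = pz - nuc(k, 2);
            double u = g * (cx * cx + cy * cy + cz * cz);
            double w = 1.0;
            if (cut) {
              double dx = pcx - nuc(k, 0), dy = pcy - nuc(k, 1),
                     dz = pcz - nuc(k, 2);
              double d = std::sqrt(dx * dx + dy * dy + dz * dz);
              if (d >= rcu) continue;
              if (d > rcl) {
                double uu = (d - rcl) * inv_span;
                w = 1.0 + uu * uu * (2.0 * uu - 3.0);
              }
            }
            v -= w * Zn[k] * pre_v * f0_kernel(u, sat, exact_erf);
          }
        }
      }
      S(i, j) = S(j, i) = s;
      T(i, j) = T(j, i) = t;
      V(i, j) = V(j, i) = v;
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// Dipole matrices <i| r |j> (electron position operator, Bohr).
// [[Rcpp::export]]
List cpp_dipole(IntegerVector off, NumericVector A, NumericVector al,
                NumericVector x, NumericVector y, NumericVector z) {
  BasisView b = view_basis(off, A, al, x, y, z);
  int n = b.nbf;
  NumericMatrix Dx(n, n), Dy(n, n), Dz(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double sx = 0, sy = 0, sz = 0;
      for (int a = b.off[i]; a < b.off[i + 1]; ++a) {
        for (int c = b.off[j]; c < b.off[j + 1]; ++c) {
          double g = b.al[a] + b.al[c];
          double xi = b.al[a] * b.al[c] / g;
          double dx = b.x[a] - b.x[c], dy = b.y[a] - b.y[c], dz = b.z[a] - b.z[c];
          double R2 = dx * dx + dy * dy + dz * dz;
          double pre = b.A[a] * b.A[c] * std::pow(PI / g, 1.5) * std::exp(-xi * R2);
          sx += pre * (b.al[a] * b.x[a] + b.al[c] * b.x[c]) / g;
          sy += pre * (b.al[a] * b.y[a] + b.al[c] * b.y[c]) / g;
          sz += pre * (b.al[a] * b.z[a] + b.al[c] * b.z[c]) / g;
        }
      }
      Dx(i, j) = Dx(j, i) = sx;
      Dy(i, j) = Dy(j, i) = sy;
      Dz(i, j) = Dz(j, i) = sz;
    }
  }
  return List::create(_["x"] = Dx, _["y"] = Dy, _["z"] = Dz);
}

// Density relevance r(rho_ij) from the absolute-value lobe representation:
// anisotropic positive Gaussians |A| exp(-ax(x-x0)^2 - ay(y-y0)^2 - az(z-z0)^2).
// The pairwise product integral factorizes per axis.
// [[Rcpp::export]]
NumericMatrix cpp_relevance(IntegerVector off, NumericVector A,
                            NumericVector ax, NumericVector ay, NumericVector az,
                            NumericVector ox, NumericVector oy, NumericVector oz) {
  int n = off.size() - 1;
  const int *o = INTEGER(off);
  NumericMatrix R(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double r = 0;
      for (int a = o[i]; a < o[i + 1]; ++a) {
        for (int c = o[j]; c < o[j + 1]; ++c) {
          double gx = ax[a] + ax[c], gy = ay[a] + ay[c], gz = az[a] + az[c];
          double dx = ox[a] - ox[c], dy = oy[a] - oy[c], dz = oz[a] - oz[c];
          double ex = ax[a] * ax[c] / gx * dx * dx +
                      ay[a] * ay[c] / gy * dy * dy +
                      az[a] * az[c] / gz * dz * dz;
          r += std::fabs(A[a]) * std::fabs(A[c]) *
               std::sqrt(PI / gx) * std::sqrt(PI / gy) * std::sqrt(PI / gz) *
               std::exp(-ex);
        }
      }
      R(i, j) = R(j, i) = r;
    }
  }
  return R;
}

// Pair tables for a list of surviving orbital pairs: for each primitive pair
// store the ERI overlap factor O_ab (includes coefficients), the product
// center r_ab and the combined exponent.
struct PairTables {
  std::vector<int> poff;
  std::vector<double> O, px, py, pz, gam;
};

static PairTables build_pair_tables(const BasisView &b, const int *pi, const int *pj,
                                    int np) {
  PairTables t;
  t.poff.resize(np + 1);
  t.poff[0] = 0;
  size_t tot = 0;
  for (int p = 0; p < np; ++p) {
    int i = pi[p], j = pj[p];
    tot += (size_t)(b.off[i + 1] - b.off[i]) * (b.off[j + 1] - b.off[j]);
    t.poff[p + 1] = (int)tot;
  }
  t.O.resize(tot); t.px.resize(tot); t.py.resize(tot); t.pz.resize(tot);
  t.gam.resize(tot);
  const double c0 = std::sqrt(2.0) * std::pow(PI, 1.25);
  size_t k = 0;
  for (int p = 0; p < np; ++p) {
    int i = pi[p], j = pj[p];
    for (int a = b.off[i]; a < b.off[i + 1]; ++a) {
      for (int c = b.off[j]; c < b.off[j + 1]; ++c) {
        double g = b.al[a] + b.al[c];
        double xi = b.al[a] * b.al[c] / g;
        double dx = b.x[a] - b.x[c], dy = b.y[a] - b.y[c], dz = b.z[a] - b.z[c];
        double R2 = dx * dx + dy * dy + dz * dz;
        t.O[k] = c0 * b.A[a] * b.A[c] * std::pow(g, -1.5) * std::exp(-xi * R2);
        t.px[k] = (b.al[a] * b.x[a] + b.al[c] * b.x[c]) / g;
        t.py[k] = (b.al[a] * b.y[a] + b.al[c] * b.y[c]) / g;
        t.pz[k] = (b.al[a] * b.z[a] + b.al[c] * b.z[c]) / g;
        t.gam[k] = g;
        ++k;
      }
    }
  }
  return t;
}

static inline double eri_pairs(const PairTables &t, int p, int q, double sat,
                               bool exact) {
  double v = 0;
  for (int a = t.poff[p]; a < t.poff[p + 1]; ++a) {
    double Oa = t.O[a];
    if (Oa == 0.0) continue;
    double g1 = t.gam[a];
    for (int c = t.poff[q]; c < t.poff[q + 1]; ++c) {
      double P = 1.0 / (1.0 / g1 + 1.0 / t.gam[c]);
      double dx = t.px[a] - t.px[c], dy = t.py[a] - t.py[c],
             dz = t.pz[a] - t.pz[c];
      double d2 = dx * dx + dy * dy + dz * dz;
      v += Oa * t.O[c] * std::sqrt(P) * f0_kernel(P * d2, sat, exact);
    }
  }
  return v;
}

// Contracted ERI (ij|kl) for four explicit orbitals (testing / oracles).
// [[Rcpp::export]]
double cpp_eri_contracted(IntegerVector off, NumericVector A, NumericVector al,
                          NumericVector x, NumericVector y, NumericVector z,
                          int i, int j, int k, int l,
                          double sat = 4.0, bool exact_erf = false) {
  BasisView b = view_basis(off, A, al, x, y, z);
  int pi[2] = {i, k}, pj[2] = {j, l};
  PairTables t = build_pair_tables(b, pi, pj, 2);
  return eri_pairs(t, 0, 1, sat, exact_erf);
}

// Screened ERI construction.
// pair_i/pair_j: surviving orbital pairs (0-based, i <= j), their screening
// centers (Bohr; arithmetic mean of the two parent atom positions) and
// relevances.  Coulomb cut-offs r_cl/r_cu in Bohr.  The combined relevance
// test uses the centre distance floored at 1 Bohr.
// [[Rcpp::export]]
List cpp_screened_eris(IntegerVector off, NumericVector A, NumericVector al,
                       NumericVector x, NumericVector y, NumericVector z,
                       IntegerVector pair_i, IntegerVector pair_j,
                       NumericMatrix pctr, NumericVector prel,
                       double rcl, double rcu, double comb_thr,
                       double sat = 4.0, bool exact_erf = false) {
  BasisView b = view_basis(off, A, al, x, y, z);
  int np = pair_i.size();
  PairTables t = build_pair_tables(b, INTEGER(pair_i), INTEGER(pair_j), np);
  std::vector<int> oi, oj, ok, ol;
  std::vector<double> val, wt;
  double inv_span = (rcu > rcl) ? 1.0 / (rcu - rcl) : 0.0;
  for (int p = 0; p < np; ++p) {
    double cx = pctr(p, 0), cy = pctr(p, 1), cz = pctr(p, 2);
    double rp = prel[p];
    for (int q = p; q < np; ++q) {
      double dx = cx - pctr(q, 0), dy = cy - pctr(q, 1), dz = cz - pctr(q, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d >= rcu) continue;
      double dfl = d < 1.0 ? 1.0 : d;
      if (rp * prel[q] / dfl <= comb_thr) continue;
      double w = 1.0;
      if (d > rcl) {
        double u = (d - rcl) * inv_span;
        w = 1.0 + u * u * (2.0 * u - 3.0);
      }
      double v = eri_pairs(t, p, q, sat, exact_erf);
      oi.push_back(pair_i[p]); oj.push_back(pair_j[p]);
      ok.push_back(pair_i[q]); ol.push_back(pair_j[q]);
      val.push_back(v); wt.push_back(w);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                      _["k"] = wrap(ok), _["l"] = wrap(ol),
                      _["value"] = wrap(val), _["weight"] = wrap(wt));
}

// Two-electron part of the Fock matrix for an arbitrary (not necessarily
// symmetric) density matrix: G = J - K/2 with
//   J_pq = sum_rs P_rs (pq|rs),  K_pq = sum_rs P_rs (pr|qs).
// The stored list holds canonical quadruplets; distinct index permutations
// are enumerated explicitly so degenerate cases are not double counted.
// [[Rcpp::export]]
NumericMatrix cpp_fock_2e(int n, IntegerVector qi, IntegerVector qj,
                          IntegerVector qk, IntegerVector ql,
                          NumericVector value, NumericVector weight,
                          NumericMatrix P) {
  NumericMatrix G(n, n);
  double *g = REAL(G);
  const double *pp = REAL(P);
  int m = qi.size();
  int perm[8][4];
  for (int e = 0; e < m; ++e) {
    double v = value[e] * weight[e];
    if (v == 0.0) continue;
    int i = qi[e], j = qj[e], k = qk[e], l = ql[e];
    int base[8][4] = {{i, j, k, l}, {j, i, k, l}, {i, j, l, k}, {j, i, l, k},
                      {k, l, i, j}, {l, k, i, j}, {k, l, j, i}, {l, k, j, i}};
    int np = 0;
    for (int p = 0; p < 8; ++p) {
      bool dup = false;
      for (int q = 0; q < np && !dup; ++q)
        dup = base[p][0] == perm[q][0] && base[p][1] == perm[q][1] &&
              base[p][2] == perm[q][2] && base[p][3] == perm[q][3];
      if (!dup) {
        perm[np][0] = base[p][0]; perm[np][1] = base[p][1];
        perm[np][2] = base[p][2]; perm[np][3] = base[p][3];
        ++np;
      }
    }
    for (int p = 0; p < np; ++p) {
      int a = perm[p][0], bq = perm[p][1], c = perm[p][2], dd = perm[p][3];
      // J: G[a,b] += v * P[c,d];  K: G[a,c] -= v/2 * P[b,d]
      g[a + n * bq] += v * pp[c + n * dd];
      g[a + n * c] -= 0.5 * v * pp[bq + n * dd];
    }
  }
  return G;
}

// Electron density on a regular grid: rho(r) = sum over retained pairs
// (i,j) of P_ij phi_i(r) phi_j(r), off-diagonal pairs counted twice.
// Grid values ordered x-outer / z-inner (Gaussian cube convention).
// [[Rcpp::export]]
NumericVector cpp_density_grid(IntegerVector off, NumericVector A, NumericVector al,
                               NumericVector x, NumericVector y, NumericVector z,
                               IntegerVector pair_i, IntegerVector pair_j,
                               NumericMatrix P, NumericVector origin,
                               double spacing, IntegerVector dims) {
  BasisView b = view_basis(off, A, al, x, y, z);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  int np = pair_i.size();
  for (int p = 0; p < np; ++p) {
    int i = pair_i[p], j = pair_j[p];
    double w = P(i, j) * (i == j ? 1.0 : 2.0);
    if (w == 0.0) continue;
    R_xlen_t idx = 0;
    for (int gx = 0; gx < nx; ++gx) {
      double X = origin[0] + gx * spacing;
      for (int gy = 0; gy < ny; ++gy) {
        double Y = origin[1] + gy * spacing;
        for (int gz = 0; gz < nz; ++gz, ++idx) {
          double Z = origin[2] + gz * spacing;
          double fi = 0, fj = 0;
          for (int a = b.off[i]; a < b.off[i + 1]; ++a) {
            double dx = X - b.x[a], dy = Y - b.y[a], dz = Z - b.z[a];
            fi += b.A[a] * std::exp(-b.al[a] * (dx * dx + dy * dy + dz * dz));
          }
          for (int a = b.off[j]; a < b.off[j + 1]; ++a) {
            double dx = X - b.x[a], dy = Y - b.y[a], dz = Z - b.z[a];
            fj += b.A[a] * std::exp(-b.al[a] * (dx * dx + dy * dy + dz * dz));
          }
          o[idx] += w * fi * fj;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
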