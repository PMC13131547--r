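// Shared force kernels for mitochondrial bead-spring chains and the
// triangulated membrane tube.  Everything here is unit-agnostic: callers pass
// parameters in any self-consistent unit system (the engine runs
// dimensionless, the standalone R wrappers pass SI).
//
// Positions are handed around as three contiguous arrays (x, y, z); Rcpp
// NumericMatrix columns are contiguous so matrix columns can be passed
// directly.

#ifndef MITOJAM_KERNELS_H
#define MITOJAM_KERNELS_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

namespace mj {

struct V3 {
  double x, y, z;
};

inline V3 operator+(const V3& a, const V3& b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 operator-(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 operator*(double s, const V3& a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

inline V3 get(const double* x, const double* y, const double* z, int i) {
  return {x[i], y[i], z[i]};
}
inline void add(double* fx, double* fy, double* fz, int i, const V3& v) {
  fx[i] += v.x; fy[i] += v.y; fz[i] += v.z;
}

// ---------------------------------------------------------------------------
// Bending of a bead triple (j - i - k), angle between consecutive bond
// tangents t1 = (r_i - r_j)/|..| and t2 = (r_k - r_i)/|..|; straight chain has
// theta = 0.  Energy per triple U = kb * theta^2 / (8 rm); forces are -grad U.
// Returns false on a degenerate (coincident-bead) triple.
inline bool bend_triple(const double* x, const double* y, const double* z,
                        int j, int i, int k, double kb, double rm,
                        double* fx, double* fy, double* fz) {
  V3 a = get(x, y, z, i) - get(x, y, z, j);   // bond j -> i
  V3 b = get(x, y, z, k) - get(x, y, z, i);   // bond i -> k
  double la = norm(a), lb = norm(b);
  if (la <= 0.0 || lb <= 0.0) return false;
  V3 ah = (1.0 / la) * a, bh = (1.0 / lb) * b;
  double c = dot(ah, bh);
  c = std::max(-1.0, std::min(1.0, c));
  double s2 = 1.0 - c * c;
  double s = (s2 > 0.0) ? std::sqrt(s2) : 0.0;
  // Analytic theta -> 0 limit: force vanishes with theta, so skip.
  if (s < 1e-8 && c > 0.0) return true;
  if (s < 1e-6) s = 1e-6;                      // guard the theta ~ pi pole
  double theta = std::acos(c);
  double dUdth = kb * theta / (4.0 * rm);
  // grad_q theta = -grad_q c / sin(theta); F_q = -dUdth * grad_q theta
  double pref = dUdth / s;
  V3 gcj = (-1.0 / la) * (bh - c * ah);        // grad_j c
  V3 gck = (1.0 / lb) * (ah - c * bh);         // grad_k c
  V3 gci = (-1.0) * (gcj + gck);
  add(fx, fy, fz, j, pref * gcj);
  add(fx, fy, fz, k, pref * gck);
  add(fx, fy, fz, i, pref * gci);
  return true;
}

// Hookean bond with rest length `rest`; F_i = -k (|r_ij| - rest) r_ij / |r_ij|.
inline bool pair_spring(const double* x, const double* y, const double* z,
                        int i, int j, double k, double rest,
                        double* fx, double* fy, double* fz) {
  V3 d = get(x, y, z, i) - get(x, y, z, j);
  double r = norm(d);
  if (r <= 0.0) return false;
  double f = -k * (r - rest) / r;
  add(fx, fy, fz, i, f * d);
  add(fx, fy, fz, j, (-f) * d);
  return true;
}

// ---------------------------------------------------------------------------
// Cell list over a static point set; cell size must be >= the interaction
// cutoff so the 27 surrounding cells cover all candidates.
struct CellGrid {
  double cs = 1.0, x0 = 0.0, y0 = 0.0, z0 = 0.0;
  int nx = 1, ny = 1, nz = 1;
  std::vector<int> head, nxt;

  void build(const double* x, const double* y, const double* z, int n, double cellsize) {
    cs = cellsize;
    nxt.assign(n, -1);
    if (n == 0) { nx = ny = nz = 1; head.assign(1, -1); return; }
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0], zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = std::max(1, (int)((xmax - x0) / cs) + 1);
    ny = std::max(1, (int)((ymax - y0) / cs) + 1);
    nz = std::max(1, (int)((zmax - z0) / cs) + 1);
    head.assign((size_t)nx * ny * nz, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(x[i], y[i], z[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  inline int clampi(int v, int hi) const { return std::max(0, std::min(hi - 1, v)); }
  inline int cell_of(double px, double py, double pz) const {
    int cx = clampi((int)std::floor((px - x0) / cs), nx);
    int cy = clampi((int)std::floor((py - y0) / cs), ny);
    int cz = clampi((int)std::floor((pz - z0) / cs), nz);
    return (cz * ny + cy) * nx + cx;
  }

  template <class F>
  void neighbors(double px, double py, double pz, F&& fun) const {
    int cx = clampi((int)std::floor((px - x0) / cs), nx);
    int cy = clampi((int)std::floor((py - y0) / cs), ny);
    int cz = clampi((int)std::floor((pz - z0) / cs), nz);
    for (int dz = -1; dz <= 1; ++dz) {
      int zz = cz + dz; if (zz < 0 || zz >= this->nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = cy + dy; if (yy < 0 || yy >= this->ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = cx + dx; if (xx < 0 || xx >= this->nx) continue;
          for (int j = head[(zz * (size_t)ny + yy) * nx + xx]; j >= 0; j = nxt[j]) fun(j);
        }
      }
    }
  }
};

// ---------------------------------------------------------------------------
// Steric volume exclusion between non-bonded beads: repulsive Hookean contact
// with range 2 rm (energy 0.5 kM (2rm - r)^2 for r < 2rm).  Beads adjacent in
// the same chain are excluded (the bonded spring handles them).
// chain[] and ord[] identify bondedness: bonded iff same chain and |ord_i -
// ord_j| == 1.
inline void steric_pair(const double* x, const double* y, const double* z,
                        int i, int j, double kM, double rm,
                        double* fx, double* fy, double* fz) {
  V3 d = get(x, y, z, i) - get(x, y, z, j);
  double r = norm(d);
  double ov = 2.0 * rm - r;
  if (ov <= 0.0 || r <= 0.0) return;
  double f = kM * ov / r;
  add(fx, fy, fz, i, f * d);
  add(fx, fy, fz, j, (-f) * d);
}

inline void steric_all(const double* x, const double* y, const double* z, int n,
                       const int* chain, const int* ord, double kM, double rm,
                       double* fx, double* fy, double* fz, bool use_cells) {
  double cutoff = 2.0 * rm;
  if (!use_cells) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (chain[i] == chain[j] && std::abs(ord[i] - ord[j]) == 1) continue;
        steric_pair(x, y, z, i, j, kM, rm, fx, fy, fz);
      }
    return;
  }
  // Candidates are gathered and sorted so the accumulation order matches the
  // all-pairs loop exactly (bit-identical forces).
  CellGrid g;
  g.build(x, y, z, n, cutoff);
  std::vector<int> js;
  for (int i = 0; i < n; ++i) {
    js.clear();
    g.neighbors(x[i], y[i], z[i], [&](int j) {
      if (j <= i) return;
      if (chain[i] == chain[j] && std::abs(ord[i] - ord[j]) == 1) return;
      js.push_back(j);
    });
    std::sort(js.begin(), js.end());
    for (int j : js) steric_pair(x, y, z, i, j, kM, rm, fx, fy, fz);
  }
}

// ---------------------------------------------------------------------------
// WCA (truncated-shifted Lennard-Jones, eps = phi0, sigma = rm, cutoff
// 2^(1/6) rm) between beads and membrane nodes.  Repulsive on the bead; the
// node receives the exact opposite.  Distances below floor_frac * rm are
// clamped (force evaluated at the floor) to avoid overflow; the number of
// clamped pairs is counted.
inline double wca_cutoff(double rm) { return std::pow(2.0, 1.0 / 6.0) * rm; }

inline void wca_all(const double* bx, const double* by, const double* bz, int nb,
                    const double* nxp, const double* nyp, const double* nzp, int nn,
                    double phi0, double rm, double floor_frac,
                    double* fbx, double* fby, double* fbz,
                    double* gx, double* gy, double* gz,
                    int* n_clamped, bool use_cells, const CellGrid* pre = nullptr) {
  double rc = wca_cutoff(rm);
  double rfloor = floor_frac * rm;
  auto apply = [&](int i, int j) {
    V3 d = {bx[i] - nxp[j], by[i] - nyp[j], bz[i] - nzp[j]};
    double r = norm(d);
    if (r >= rc) return;
    double reval = r;
    if (reval < rfloor) { reval = rfloor; ++(*n_clamped); }
    double s = reval / rm;
    double fmag = 24.0 * phi0 / rm * (2.0 * std::pow(s, -13.0) - std::pow(s, -7.0));
    V3 dir = (r > 0.0) ? (1.0 / r) * d : V3{1.0, 0.0, 0.0};
    add(fbx, fby, fbz, i, fmag * dir);
    add(gx, gy, gz, j, (-fmag) * dir);
  };
  if (!use_cells) {
    for (int i = 0; i < nb; ++i)
      for (int j = 0; j < nn; ++j) apply(i, j);
    return;
  }
  CellGrid local;
  const CellGrid* g = pre;
  if (!g) {
    local.build(nxp, nyp, nzp, nn, rc);
    g = &local;
  }
  std::vector<int> js;
  for (int i = 0; i < nb; ++i) {
    js.clear();
    g->neighbors(bx[i], by[i], bz[i], [&](int j) { js.push_back(j); });
    std::sort(js.begin(), js.end());
    for (int j : js) apply(i, j);
  }
}

// ---------------------------------------------------------------------------
// Signed dihedral over the torsion p1-p2-p3-p4 (hinge edge p2-p3, flanking
// nodes p1, p4) and its analytic gradient wrt the four points.
inline double dihedral(const V3& p1, const V3& p2, const V3& p3, const V3& p4) {
  V3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
  V3 m = cross(b1, b2), n = cross(b2, b3);
  double nb2 = norm(b2);
  double xc = dot(m, n);
  double yc = dot(cross(m, n), b2) / (nb2 > 0 ? nb2 : 1.0);
  return std::atan2(yc, xc);
}

inline bool dihedral_grad(const V3& p1, const V3& p2, const V3& p3, const V3& p4,
                          V3 g[4]) {
  V3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
  V3 m = cross(b1, b2), n = cross(b2, b3);
  double nb2 = norm(b2), m2 = dot(m, m), n2 = dot(n, n);
  if (nb2 <= 0.0 || m2 <= 0.0 || n2 <= 0.0) return false;
  V3 F1 = (-nb2 / m2) * m;
  V3 F4 = (nb2 / n2) * n;
  double t1 = dot(b1, b2) / (nb2 * nb2);
  double t2 = dot(b3, b2) / (nb2 * nb2);
  g[0] = F1;
  g[3] = F4;
  g[1] = (-1.0 - t1) * F1 + t2 * F4;
  g[2] = t1 * F1 + (-1.0 - t2) * F4;
  return true;
}

// Hinge bending: E = kb * w * (1 - cos(theta - theta0)) per hinge, with the
// geometric weight w = |e_ij| / (A_ij1 + A_ij2) frozen at the reference
// configuration.  hi/hj are the hinge edge nodes, hk/hl the flanking nodes.
inline bool hinge_forces(const double* x, const double* y, const double* z,
                         const int* hi, const int* hj, const int* hk, const int* hl,
                         const double* w, const double* th0, int nh, double kb,
                         double* fx, double* fy, double* fz) {
  for (int h = 0; h < nh; ++h) {
    V3 p1 = get(x, y, z, hk[h]);
    V3 p2 = get(x, y, z, hi[h]);
    V3 p3 = get(x, y, z, hj[h]);
    V3 p4 = get(x, y, z, hl[h]);
    double th = dihedral(p1, p2, p3, p4);
    double dlt = th - th0[h];
    while (dlt > M_PI) dlt -= 2.0 * M_PI;
    while (dlt < -M_PI) dlt += 2.0 * M_PI;
    V3 g[4];
    if (!dihedral_grad(p1, p2, p3, p4, g)) return false;
    double coef = -kb * w[h] * std::sin(dlt);   // -dE/dtheta
    add(fx, fy, fz, hk[h], coef * g[0]);
    add(fx, fy, fz, hi[h], coef * g[1]);
    add(fx, fy, fz, hj[h], coef * g[2]);
    add(fx, fy, fz, hl[h], coef * g[3]);
  }
  return true;
}

// Global area elasticity: U = 0.5 kAE A0 (A/A0 - 1)^2;
// F_i = -kAE (A/A0 - 1) sum_f grad_i A_f with grad_i A_f = 0.5 n_f x (r_k - r_j).
// Returns the current total area (negative on a degenerate face).
inline double area_forces(const double* x, const double* y, const double* z,
                          const int* fi, const int* fj, const int* fk, int nf,
                          double A0, double kAE,
                          double* fx, double* fy, double* fz) {
  double A = 0.0;
  std::vector<double> af(nf);
  for (int f = 0; f < nf; ++f) {
    V3 ri = get(x, y, z, fi[f]), rj = get(x, y, z, fj[f]), rk = get(x, y, z, fk[f]);
    V3 nvec = cross(rj - ri, rk - ri);
    double a2 = norm(nvec);
    if (a2 <= 0.0) return -1.0;
    af[f] = 0.5 * a2;
    A += af[f];
  }
  double pref = -kAE * (A / A0 - 1.0);
  if (pref != 0.0) {
    for (int f = 0; f < nf; ++f) {
      V3 ri = get(x, y, z, fi[f]), rj = get(x, y, z, fj[f]), rk = get(x, y, z, fk[f]);
      V3 nvec = cross(rj - ri, rk - ri);
      V3 nh = (1.0 / norm(nvec)) * nvec;
      add(fx, fy, fz, fi[f], pref * (0.5 * cross(nh, rk - rj)));
      add(fx, fy, fz, fj[f], pref * (0.5 * cross(nh, ri - rk)));
      add(fx, fy, fz, fk[f], pref * (0.5 * cross(nh, rj - ri)));
    }
  }
  return A;
}

// Cytoskeletal (spectrin/actin) edge springs with per-edge rest length and
// stiffness.
inline bool edge_forces(const double* x, const double* y, const double* z,
                        const int* ea, const int* eb, const double* rest,
                        const double* kk, int ne,
                        double* fx, double* fy, double* fz) {
  for (int e = 0; e < ne; ++e)
    if (!pair_spring(x, y, z, ea[e], eb[e], kk[e], rest[e], fx, fy, fz)) return false;
  return true;
}

}  // namespace mj

#endif
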