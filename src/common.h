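#ifndef HEMOFLOW_COMMON_H
#define HEMOFLOW_COMMON_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>
#include <sstream>

// All quantities in reduced DPD units (unit particle mass).

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// splitmix64: derive independent stream seeds from one master seed so that
// toggling one subsystem does not perturb another subsystem's draws.
inline std::uint64_t splitmix64(std::uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  std::uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct DpdPar {
  double a = 4.0, gamma = 30.0, rc = 1.5, kBT = 0.0945, s = 0.5, n = 2.96, g = 0.1;
  double sigma() const { return std::sqrt(2.0 * gamma * kBT); }
  double wD(double r) const {
    double om = 1.0 - r / rc;
    if (om <= 0.0) return 0.0;
    if (s == 0.5) return std::sqrt(om);
    if (s == 1.0) return om;
    if (s == 2.0) return om * om;
    return std::pow(om, s);
  }
};

struct MembPar {
  // l0/lm live on the mesh template; the rest are global membrane parameters.
  double p = 0.004, kb = 7.56, theta0 = 0.0, ka = 4900.0, kv = 5000.0;
  double gT = 10.0, gC = 5.0, kBT = 0.0945;
};

// WLC spring tension dV/dl for V = kBT*lm*(3x^2-2x^3)/(4p(1-x)), x = l/lm.
inline double wlc_dVdl(double x, double kBT, double p) {
  double om = 1.0 - x;
  return kBT / (4.0 * p) * (6.0 * x - 9.0 * x * x + 4.0 * x * x * x) / (om * om);
}
inline double wlc_energy(double x, double kBT, double p, double lm) {
  return kBT * lm / (4.0 * p) * (3.0 * x * x - 2.0 * x * x * x) / (1.0 - x);
}
// Per-triangle area-repulsion constant C (energy C/A_alpha) that makes a flat
// equilateral sheet with all springs at l0 = x0*lm stress free.
inline double tri_repulsion_C(double x0, double lm, double kBT, double p) {
  double om = 1.0 - x0;
  return 3.0 * std::sqrt(3.0) * kBT * lm * lm * lm * std::pow(x0, 4) *
         (4.0 * x0 * x0 - 9.0 * x0 + 6.0) / (64.0 * p * om * om);
}

// Wetted-domain geometry with inside-positive signed distance.
// type 0: none (periodic box, no walls); 1: tube along z; 2: planar Y-bifurcation.
struct Geom {
  int type = 0;
  double R = 0.0;                       // tube radius
  double Rp = 0.0, zj = 0.0;            // bifurcation: parent radius, junction z
  double d1[3] = {0, 0, 1}, d2[3] = {0, 0, 1};
  double Rd[2] = {0, 0}, Ld[2] = {0, 0};

  double sdf(const double* pnt) const {
    if (type == 0) return 1e30;
    if (type == 1) return R - std::sqrt(pnt[0] * pnt[0] + pnt[1] * pnt[1]);
    // bifurcation: union (max) of parent (capped at junction) and daughters
    double rho = std::sqrt(pnt[0] * pnt[0] + pnt[1] * pnt[1]);
    double sp = std::min(Rp - rho, zj - pnt[2]);
    double best = sp;
    for (int b = 0; b < 2; ++b) {
      const double* dd = (b == 0) ? d1 : d2;
      double q[3] = {pnt[0], pnt[1], pnt[2] - zj};
      double t = dot3(q, dd);
      double perp[3] = {q[0] - t * dd[0], q[1] - t * dd[1], q[2] - t * dd[2]};
      double sb = std::min(Rd[b] - norm3(perp), t);
      if (sb > best) best = sb;
    }
    return best;
  }

  // branch id of a point: 0 parent, 1/2 daughters (largest sdf wins)
  int branch(const double* pnt) const {
    if (type != 2) return 0;
    double rho = std::sqrt(pnt[0] * pnt[0] + pnt[1] * pnt[1]);
    double sp = std::min(Rp - rho, zj - pnt[2]);
    int best = 0; double sb0 = sp;
    for (int b = 0; b < 2; ++b) {
      const double* dd = (b == 0) ? d1 : d2;
      double q[3] = {pnt[0], pnt[1], pnt[2] - zj};
      double t = dot3(q, dd);
      double perp[3] = {q[0] - t * dd[0], q[1] - t * dd[1], q[2] - t * dd[2]};
      double sb = std::min(Rd[b] - norm3(perp), t);
      if (sb > sb0) { sb0 = sb; best = b + 1; }
    }
    return best;
  }

  // flow direction (unit) at a point, used for the body-force driver
  void flow_dir(const double* pnt, double* out) const {
    int b = branch(pnt);
    if (b == 0) { out[0] = 0; out[1] = 0; out[2] = 1; return; }
    const double* dd = (b == 1) ? d1 : d2;
    out[0] = dd[0]; out[1] = dd[1]; out[2] = dd[2];
  }
};

struct Outlet {
  double o[3] = {0, 0, 0};   // point on the outflow plane
  double dir[3] = {0, 0, 1}; // outward unit normal (flow direction)
  double Ldel = 3.0;         // axial extent of the cell-deletion region upstream
  double P = 0.5;            // removal probability (particle reflected w.p. 1-P)
  double rho_target = 2.96;
  double signed_s(const double* pnt) const {
    double q[3] = {pnt[0] - o[0], pnt[1] - o[1], pnt[2] - o[2]};
    return dot3(q, dir);
  }
};

struct MeshT {
  int nv = 0;
  std::vector<int> springs;    // 2 per spring (local 0-based)
  std::vector<int> triangles;  // 3 per triangle (outward orientation)
  std::vector<int> dihedrals;  // 4 per dihedral: i j k l, shared edge (i,j),
                               // wings k (tri i,j,k) and l (tri j,i,l)
  double l0 = 1.0, lm = 2.2;
};

#endif
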