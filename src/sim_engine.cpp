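// The simulation engine: particle state, DPD pair forces through a uniform
// cell list, membrane bonded forces, velocity-Verlet integration and the open
// boundary condition (OBC) machinery -- periodic generating region with ghost
// zones, one-way coupling across the copy border, fluid/cell duplication with
// slaved motion, adaptive probabilistic outflow membrane and cell dissolution.
//
// Step hook order (after the drift): bounce-back -> cell dissolution ->
// outflow membrane -> controller update -> duplication (crossings recorded at
// the periodic wrap are materialized here) -> ghost regeneration -> forces.
#include "common.h"
#include <deque>
using namespace Rcpp;

void membrane_bonded_forces(const double* pos, double* frc, int vidx0,
                            const MeshT& M, const MembPar& mp, double A0,
                            double V0, bool do_elastic, bool do_bend,
                            bool do_av, double* out);
void membrane_viscous_forces(const double* pos, const double* vel, double* frc,
                             int vidx0, const MeshT& M, const MembPar& mp,
                             double dt, std::mt19937_64* rng);

enum Cat { GEN = 0, MAIN = 1, WALLGEN = 2, WALLMAIN = 3, GHOST = 4, SLAVED = 5 };
enum Spec { FLUID = 0, WALL = 1, MEMB = 2 };

struct Sim {
  // particles (real particles [0, nReal), ghosts appended [nReal, n))
  std::vector<double> pos, vel, frc, vir;
  std::vector<int> spc, reg, cel;
  int nReal = 0;

  // cells
  struct Cell {
    int first = 0, nv = 0, tmpl = 0, reg = 1;
    double A0 = 0, V0 = 0, offz = 0;
    int master = -1;
    char slaved = 0, alive = 1;
    char latch = 0; // set while near the periodic seam: one duplication per transit
  };
  std::vector<Cell> cells;
  std::vector<MeshT> templates;

  // physics / layout
  DpdPar fp;
  MembPar mp;
  Geom geom;
  double dt = 0.005, mass = 1.0;
  double box[6] = {0, 0, 0, 0, 0, 0};
  bool per[3] = {false, false, false};
  bool obc = false, therm = true;
  double Lg = 0, zone_w = 1.5; // generating region length, ghost zone width
  std::vector<Outlet> outlets;
  std::vector<int> outlet_branch;
  double h = 0.05, Vmain = 1.0;
  int smooth_win = 100;
  double gfac[3] = {1, 1, 1}; // per-branch body-force factors (parent, d1, d2)
  double gmain = 1.0; // main-region body-force factor (0 = pressure-driven main)
  double limit_disp = 0.0;
  long step_idx = 0;

  std::mt19937_64 rng_fluid, rng_memb, rng_out;

  // controller state
  std::deque<double> rho_hist;

  // logs / accumulators
  std::vector<double> log_rho, log_rho_smooth;
  std::vector<double> log_P; // ncol = n outlets
  std::vector<double> exits; // step, outlet, cell, nv
  std::vector<long> removed_fluid; // per outlet, cumulative
  long removed_upstream = 0;       // main fluid absorbed at the copy border
  long inserted_fluid = 0, inserted_cells = 0;
  long wall_clamp_warnings = 0;
  // sampled rows
  int vel_nbins = 0;
  double vel_zmin = 0, vel_zmax = 0, vel_rmax = 1;
  std::vector<double> prof_sum, prof_cnt; // samples x nbins
  int pres_nslabs = 0;
  double pres_zmin = 0, pres_zmax = 0, slab_vol = 1;
  std::vector<double> pres_rows;
  std::vector<double> temp_rows;    // mean KE per fluid particle
  std::vector<double> mom_rows;     // total momentum (3)
  std::vector<double> count_rows;   // main fluid+membrane count
  std::vector<double> sample_steps;

  bool is_slaved_particle(int i) const {
    return cel[i] >= 0 && cells[cel[i]].slaved;
  }
  int cat(int i) const {
    if (reg[i] == 9) return GHOST;
    if (spc[i] == WALL) return reg[i] == 0 ? WALLGEN : WALLMAIN;
    if (is_slaved_particle(i)) return SLAVED;
    return reg[i] == 0 ? GEN : MAIN;
  }
  static bool receives(int tc, int sc) {
    if (tc == GEN) return sc == GEN || sc == WALLGEN || sc == GHOST;
    if (tc == MAIN) return sc != GHOST;
    return false;
  }
  bool integrable(int i) const {
    return spc[i] != WALL && reg[i] != 9 && !is_slaved_particle(i);
  }

  double com_z(const Cell& C) const {
    double s = 0;
    for (int k = 0; k < C.nv; ++k) s += pos[3 * (C.first + k) + 2];
    return s / C.nv;
  }

  // ---------------- forces ----------------
  void compute_forces() {
    int n = (int)pos.size() / 3;
    std::fill(frc.begin(), frc.end(), 0.0);
    std::fill(vir.begin(), vir.end(), 0.0);

    // body force along the local flow direction
    for (int i = 0; i < nReal; ++i) {
      if (!integrable(i)) continue;
      double dir[3];
      geom.flow_dir(&pos[3 * i], dir);
      int b = geom.branch(&pos[3 * i]);
      double gg = fp.g * gfac[b];
      if (reg[i] == 1) gg *= gmain;
      for (int c = 0; c < 3; ++c) frc[3 * i + c] += gg * dir[c];
    }

    // --- DPD pair forces via cell list ---
    double lo[3] = {box[0], box[2], box[4]}, hi[3] = {box[1], box[3], box[5]};
    double L[3];
    int nb[3];
    for (int c = 0; c < 3; ++c) {
      L[c] = hi[c] - lo[c];
      nb[c] = std::max(1, (int)std::floor(L[c] / fp.rc));
      if (per[c] && nb[c] < 3)
        stop("periodic dimension too small for the cell list (need >= 3 bins)");
    }
    // bin-sorted cell list split into RECEIVERS (integrable fluid/membrane
    // of either region) and SOURCE-ONLY particles (walls, ghosts, slaved
    // duplicates, which exert forces but never receive them): receiver-
    // receiver pairs run a half stencil, receiver-source pairs a full
    // stencil, and source-source work is skipped entirely.
    const int nbins = nb[0] * nb[1] * nb[2];
    std::vector<int> pcat(n);
    for (int i = 0; i < n; ++i) pcat[i] = cat(i);
    // wrapped coordinates for binning and pair distances (periodic dims);
    // raw positions stay unwrapped (whole-cell wrapping keeps meshes intact)
    std::vector<double> wp(pos);
    for (int c = 0; c < 3; ++c)
      if (per[c])
        for (int i = 0; i < n; ++i) {
          double& x = wp[3 * i + c];
          x = x - L[c] * std::floor((x - lo[c]) / L[c]);
        }
    std::vector<int> bid(n);
    for (int i = 0; i < n; ++i) {
      int b[3];
      for (int c = 0; c < 3; ++c) {
        int k = (int)std::floor((wp[3 * i + c] - lo[c]) / (L[c] / nb[c]));
        if (k < 0) k = 0;
        if (k >= nb[c]) k = nb[c] - 1;
        b[c] = k;
      }
      bid[i] = (b[2] * nb[1] + b[1]) * nb[0] + b[0];
    }
    auto is_receiver = [&](int i) {
      int c = pcat[i];
      return c == GEN || c == MAIN;
    };
    // gather each group into per-bin contiguous slices
    struct Sorted {
      std::vector<int> start, orig, cat_, cel_;
      std::vector<double> p, v;
    };
    auto gather = [&](bool receivers) {
      Sorted S;
      S.start.assign(nbins + 1, 0);
      for (int i = 0; i < n; ++i)
        if (is_receiver(i) == receivers) ++S.start[bid[i] + 1];
      for (int b = 0; b < nbins; ++b) S.start[b + 1] += S.start[b];
      int m = S.start[nbins];
      S.orig.resize(m); S.cat_.resize(m); S.cel_.resize(m);
      S.p.resize(3 * m); S.v.resize(3 * m);
      std::vector<int> fill(S.start.begin(), S.start.end() - 1);
      for (int i = 0; i < n; ++i) {
        if (is_receiver(i) != receivers) continue;
        int k = fill[bid[i]]++;
        S.orig[k] = i;
        S.cat_[k] = pcat[i];
        S.cel_[k] = cel[i];
        for (int c = 0; c < 3; ++c) {
          S.p[3 * k + c] = wp[3 * i + c];
          S.v[3 * k + c] = vel[3 * i + c];
        }
      }
      return S;
    };
    Sorted A = gather(true), B = gather(false);
    int nA = (int)A.orig.size();
    std::vector<double> afrc(3 * nA, 0.0), avir(nA, 0.0);

    const int stencil[14][3] = {{0, 0, 0}, {1, 0, 0}, {-1, 1, 0}, {0, 1, 0},
                                {1, 1, 0}, {-1, -1, 1}, {0, -1, 1}, {1, -1, 1},
                                {-1, 0, 1}, {0, 0, 1}, {1, 0, 1}, {-1, 1, 1},
                                {0, 1, 1}, {1, 1, 1}};
    const double rc2 = fp.rc * fp.rc;
    const double sig = therm ? fp.sigma() : 0.0;
    const double isqdt = 1.0 / std::sqrt(dt);
    // uniform pair noise with unit variance (Groot-Warren: equilibrium
    // properties identical to Gaussian noise, much cheaper per pair)
    const double u2sig = std::sqrt(3.0) * 2.0;
    auto xi_draw = [&]() {
      return u2sig * ((double)(rng_fluid() >> 11) * (1.0 / 9007199254740992.0) - 0.5);
    };
    // receives() as a flat table indexed by [target][source]
    bool rtab[6][6];
    for (int tc = 0; tc < 6; ++tc)
      for (int sc = 0; sc < 6; ++sc) rtab[tc][sc] = receives(tc, sc);

    auto wrap_bin = [&](int& cx, int& cy, int& cz, double& sx, double& sy,
                        double& sz) {
      sx = sy = sz = 0;
      if (cx < 0) { if (!per[0]) return false; cx += nb[0]; sx = L[0]; }
      else if (cx >= nb[0]) { if (!per[0]) return false; cx -= nb[0]; sx = -L[0]; }
      if (cy < 0) { if (!per[1]) return false; cy += nb[1]; sy = L[1]; }
      else if (cy >= nb[1]) { if (!per[1]) return false; cy -= nb[1]; sy = -L[1]; }
      if (cz < 0) { if (!per[2]) return false; cz += nb[2]; sz = L[2]; }
      else if (cz >= nb[2]) { if (!per[2]) return false; cz -= nb[2]; sz = -L[2]; }
      return true;
    };

    for (int bz = 0; bz < nb[2]; ++bz)
      for (int by = 0; by < nb[1]; ++by)
        for (int bx = 0; bx < nb[0]; ++bx) {
          int b1 = (bz * nb[1] + by) * nb[0] + bx;
          if (A.start[b1] == A.start[b1 + 1]) continue;
          // receiver-receiver: half stencil
          for (int sdx = 0; sdx < 14; ++sdx) {
            int cx = bx + stencil[sdx][0], cy = by + stencil[sdx][1],
                cz = bz + stencil[sdx][2];
            double sx, sy, sz;
            if (!wrap_bin(cx, cy, cz, sx, sy, sz)) continue;
            int b2 = (cz * nb[1] + cy) * nb[0] + cx;
            bool same = (sdx == 0);
            int j0 = A.start[b2], j1 = A.start[b2 + 1];
            if (j0 == j1) continue;
            for (int ki = A.start[b1]; ki < A.start[b1 + 1]; ++ki) {
              const double pix = A.p[3 * ki] + sx, piy = A.p[3 * ki + 1] + sy,
                           piz = A.p[3 * ki + 2] + sz;
              const int cati = A.cat_[ki], celi = A.cel_[ki];
              for (int kj = same ? ki + 1 : j0; kj < j1; ++kj) {
                double dx = pix - A.p[3 * kj], dy = piy - A.p[3 * kj + 1],
                       dz = piz - A.p[3 * kj + 2];
                double r2 = dx * dx + dy * dy + dz * dz;
                if (r2 >= rc2) continue;
                bool ri = rtab[cati][A.cat_[kj]], rj = rtab[A.cat_[kj]][cati];
                if (!ri && !rj) continue;
                if (celi >= 0 && celi == A.cel_[kj]) continue;
                double r = std::sqrt(r2);
                if (r < 1e-10) stop("coincident particles in DPD pair force");
                double inv = 1.0 / r;
                double ex = dx * inv, ey = dy * inv, ez = dz * inv;
                double om = 1.0 - r / fp.rc;
                double wd = fp.wD(r);
                double edv = ex * (A.v[3 * ki] - A.v[3 * kj]) +
                             ey * (A.v[3 * ki + 1] - A.v[3 * kj + 1]) +
                             ez * (A.v[3 * ki + 2] - A.v[3 * kj + 2]);
                double F = fp.a * om - fp.gamma * wd * edv;
                if (sig > 0.0)
                  F += sig * std::sqrt(wd) * xi_draw() * isqdt;
                if (ri) {
                  afrc[3 * ki] += F * ex;
                  afrc[3 * ki + 1] += F * ey;
                  afrc[3 * ki + 2] += F * ez;
                }
                if (rj) {
                  afrc[3 * kj] -= F * ex;
                  afrc[3 * kj + 1] -= F * ey;
                  afrc[3 * kj + 2] -= F * ez;
                }
                avir[ki] += r * F / 6.0; // per-particle virial share
                avir[kj] += r * F / 6.0;
              }
            }
          }
          // receiver-source: full stencil, force applied to the receiver only
          for (int ox = -1; ox <= 1; ++ox)
            for (int oy = -1; oy <= 1; ++oy)
              for (int oz = -1; oz <= 1; ++oz) {
                int cx = bx + ox, cy = by + oy, cz = bz + oz;
                double sx, sy, sz;
                if (!wrap_bin(cx, cy, cz, sx, sy, sz)) continue;
                int b2 = (cz * nb[1] + cy) * nb[0] + cx;
                int j0 = B.start[b2], j1 = B.start[b2 + 1];
                if (j0 == j1) continue;
                for (int ki = A.start[b1]; ki < A.start[b1 + 1]; ++ki) {
                  const double pix = A.p[3 * ki] + sx,
                               piy = A.p[3 * ki + 1] + sy,
                               piz = A.p[3 * ki + 2] + sz;
                  const int cati = A.cat_[ki], celi = A.cel_[ki];
                  for (int kj = j0; kj < j1; ++kj) {
                    double dx = pix - B.p[3 * kj], dy = piy - B.p[3 * kj + 1],
                           dz = piz - B.p[3 * kj + 2];
                    double r2 = dx * dx + dy * dy + dz * dz;
                    if (r2 >= rc2) continue;
                    if (!rtab[cati][B.cat_[kj]]) continue;
                    if (celi >= 0 && celi == B.cel_[kj]) continue;
                    double r = std::sqrt(r2);
                    if (r < 1e-10)
                      stop("coincident particles in DPD pair force");
                    double inv = 1.0 / r;
                    double ex = dx * inv, ey = dy * inv, ez = dz * inv;
                    double om = 1.0 - r / fp.rc;
                    double wd = fp.wD(r);
                    double edv = ex * (A.v[3 * ki] - B.v[3 * kj]) +
                                 ey * (A.v[3 * ki + 1] - B.v[3 * kj + 1]) +
                                 ez * (A.v[3 * ki + 2] - B.v[3 * kj + 2]);
                    double F = fp.a * om - fp.gamma * wd * edv;
                    if (sig > 0.0)
                      F += sig * std::sqrt(wd) * xi_draw() * isqdt;
                    afrc[3 * ki] += F * ex;
                    afrc[3 * ki + 1] += F * ey;
                    afrc[3 * ki + 2] += F * ez;
                    avir[ki] += r * F / 6.0;
                  }
                }
              }
        }
    // scatter back to original ordering
    for (int k = 0; k < nA; ++k) {
      int i = A.orig[k];
      frc[3 * i] += afrc[3 * k];
      frc[3 * i + 1] += afrc[3 * k + 1];
      frc[3 * i + 2] += afrc[3 * k + 2];
      if (i < nReal) vir[i] += avir[k];
    }

    // --- membrane bonded + viscous forces (skipped for slaved duplicates) ---
    double outE[6];
    for (size_t ic = 0; ic < cells.size(); ++ic) {
      Cell& C = cells[ic];
      if (!C.alive || C.slaved) continue;
      const MeshT& M = templates[C.tmpl];
      membrane_bonded_forces(pos.data(), frc.data(), C.first, M, mp, C.A0, C.V0,
                             true, true, true, outE);
      membrane_viscous_forces(pos.data(), vel.data(), frc.data(), C.first, M,
                              mp, dt, therm ? &rng_memb : nullptr);
    }
  }

  // ---------------- step ----------------
  void check_finite() {
    for (int i = 0; i < nReal; ++i)
      for (int c = 0; c < 3; ++c)
        if (!std::isfinite(pos[3 * i + c]) || !std::isfinite(vel[3 * i + c]))
          stop("non-finite position/velocity at step %ld, particle %d "
               "(instability: reduce dt)", step_idx, i + 1);
  }

  void bounce_back(const std::vector<double>& xold) {
    if (geom.type == 0) return;
    for (int i = 0; i < nReal; ++i) {
      if (spc[i] == WALL || reg[i] == 9 || is_slaved_particle(i)) continue;
      double* p = &pos[3 * i];
      if (geom.sdf(p) >= 0) continue;
      // bisect the crossing point along the incoming trajectory
      const double* p0 = &xold[3 * i];
      double a = 0.0, b = 1.0, q[3];
      if (geom.sdf(p0) < 0) {
        // started outside (deep penetration): clamp to surface along -gradient
        double g[3], eps = 1e-4, base = geom.sdf(p);
        for (int c = 0; c < 3; ++c) {
          double pp[3] = {p[0], p[1], p[2]};
          pp[c] += eps;
          g[c] = (geom.sdf(pp) - base) / eps;
        }
        double gn = norm3(g);
        if (gn > 1e-12)
          for (int c = 0; c < 3; ++c) p[c] += (-base + 0.01) * g[c] / gn;
        for (int c = 0; c < 3; ++c) vel[3 * i + c] = -vel[3 * i + c];
        ++wall_clamp_warnings;
        continue;
      }
      for (int it = 0; it < 30; ++it) {
        double m = 0.5 * (a + b);
        for (int c = 0; c < 3; ++c) q[c] = p0[c] + m * (p[c] - p0[c]);
        if (geom.sdf(q) >= 0) a = m; else b = m;
      }
      for (int c = 0; c < 3; ++c) q[c] = p0[c] + a * (p[c] - p0[c]);
      // reflect position across the crossing point, reverse full velocity
      for (int c = 0; c < 3; ++c) {
        p[c] = 2.0 * q[c] - p[c];
        vel[3 * i + c] = -vel[3 * i + c];
      }
      if (geom.sdf(p) < 0) { // corner case: clamp to the crossing point
        for (int c = 0; c < 3; ++c) p[c] = q[c];
        ++wall_clamp_warnings;
      }
    }
  }

  void step(bool sample) {
    // drop ghosts from the previous step
    pos.resize(3 * nReal); vel.resize(3 * nReal); frc.resize(3 * nReal);
    vir.resize(nReal); spc.resize(nReal); reg.resize(nReal); cel.resize(nReal);

    // 1. half kick + drift
    for (int i = 0; i < nReal; ++i)
      if (integrable(i))
        for (int c = 0; c < 3; ++c) vel[3 * i + c] += 0.5 * dt * frc[3 * i + c] / mass;
    std::vector<double> xold(pos);
    for (int i = 0; i < nReal; ++i) {
      if (!integrable(i)) continue;
      for (int c = 0; c < 3; ++c) {
        double dx = dt * vel[3 * i + c];
        if (limit_disp > 0) dx = std::max(-limit_disp, std::min(limit_disp, dx));
        pos[3 * i + c] += dx;
      }
    }
    check_finite();

    // 2. periodic wrap; record copy-border crossings (materialized later)
    std::vector<double> dup_fluid; // pos(3), vel(3) per crossing
    std::vector<int> dup_cells;
    if (obc) {
      for (int i = 0; i < nReal; ++i) {
        if (spc[i] != FLUID || reg[i] != 0) continue;
        if (pos[3 * i + 2] >= Lg) {
          dup_fluid.insert(dup_fluid.end(),
                           {pos[3 * i], pos[3 * i + 1], pos[3 * i + 2],
                            vel[3 * i], vel[3 * i + 1], vel[3 * i + 2]});
          pos[3 * i + 2] -= Lg;
        } else if (pos[3 * i + 2] < 0) {
          pos[3 * i + 2] += Lg;
        }
      }
      for (size_t ic = 0; ic < cells.size(); ++ic) {
        Cell& C = cells[ic];
        if (!C.alive || C.reg != 0) continue;
        double cz = com_z(C);
        if (cz >= Lg) { // whole-cell wrap; duplicate once per transit
          if (!C.latch) {
            // safety: a still-slaved duplicate of this master would teleport
            // with the wrap -- release it first
            for (auto& D : cells)
              if (D.alive && D.slaved && D.master == (int)ic) D.slaved = 0;
            dup_cells.push_back((int)ic);
          }
          C.latch = 1; // COM jitter across the seam must not re-duplicate
          for (int k = 0; k < C.nv; ++k) pos[3 * (C.first + k) + 2] -= Lg;
        } else if (cz < 0) {
          C.latch = 1; // upstream wrap: next downstream wrap is not a transit
          for (int k = 0; k < C.nv; ++k) pos[3 * (C.first + k) + 2] += Lg;
        } else if (cz > 0.25 * Lg && cz < 0.75 * Lg) {
          C.latch = 0; // safely mid-transit: re-arm the duplication latch
        }
      }
    } else {
      for (int c = 0; c < 3; ++c) {
        if (!per[c]) continue;
        double lo = box[2 * c], L = box[2 * c + 1] - box[2 * c];
        for (int i = 0; i < nReal; ++i) {
          if (spc[i] == WALL || cel[i] >= 0) continue;
          double& x = pos[3 * i + c];
          x = x - L * std::floor((x - lo) / L);
        }
        if (c == 2) { // whole-cell wrap along the flow axis
          for (size_t ic = 0; ic < cells.size(); ++ic) {
            Cell& C = cells[ic];
            if (!C.alive) continue;
            double cz = com_z(C);
            double sh = -L * std::floor((cz - lo) / L);
            if (sh != 0)
              for (int k = 0; k < C.nv; ++k) pos[3 * (C.first + k) + 2] += sh;
          }
        }
      }
    }

    // 3. bounce-back at the frozen walls
    bounce_back(xold);

    std::vector<char> dead(nReal, 0);
    if (obc) {
      // 3b. absorption at the copy border: the duplication of generating
      // particles counts *gross* downstream crossings, so the thermal
      // back-flux must be absorbed symmetrically -- main-domain fluid that
      // drifts upstream of the copy border is removed. Without this the
      // border over-feeds the main domain by the two-way thermal flux and
      // the main flow runs far above the pilot flow.
      for (int i = 0; i < nReal; ++i) {
        if (spc[i] == FLUID && reg[i] == 1 && pos[3 * i + 2] < Lg) {
          dead[i] = 1;
          ++removed_upstream;
        }
      }
      // 4. cell dissolution in the outlet deletion regions
      for (size_t ic = 0; ic < cells.size(); ++ic) {
        Cell& C = cells[ic];
        if (!C.alive || C.slaved || C.reg != 1) continue;
        for (size_t k = 0; k < outlets.size(); ++k) {
          bool allin = true;
          for (int v = 0; v < C.nv && allin; ++v) {
            const double* pv = &pos[3 * (C.first + v)];
            if (outlets[k].signed_s(pv) < -outlets[k].Ldel) allin = false;
            else if (geom.type == 2 && geom.branch(pv) != outlet_branch[k])
              allin = false;
          }
          if (allin) {
            // destroy topology, retag vertices as fluid in place
            for (int v = 0; v < C.nv; ++v) {
              spc[C.first + v] = FLUID;
              cel[C.first + v] = -1;
            }
            C.alive = 0;
            exits.push_back((double)step_idx);
            exits.push_back((double)k + 1);
            exits.push_back((double)ic + 1);
            exits.push_back((double)C.nv);
            break;
          }
        }
      }
      // 5. probabilistic outflow membrane (fluid only; membrane vertices are
      //    exempt until their cell dissolves). P is the reflection-survival
      //    probability: crossing particles are reflected back with
      //    probability P and removed otherwise.
      std::uniform_real_distribution<double> U01(0.0, 1.0);
      for (int i = 0; i < nReal; ++i) {
        if (spc[i] != FLUID || reg[i] != 1 || dead[i]) continue;
        for (size_t k = 0; k < outlets.size(); ++k) {
          double s = outlets[k].signed_s(&pos[3 * i]);
          if (s <= 0) continue;
          if (U01(rng_out) < outlets[k].P) {
            // specular reflection: mirror position, negate normal velocity
            double vn = dot3(&vel[3 * i], outlets[k].dir);
            for (int c = 0; c < 3; ++c) {
              pos[3 * i + c] -= 2.0 * s * outlets[k].dir[c];
              vel[3 * i + c] -= 2.0 * vn * outlets[k].dir[c];
            }
          } else {
            dead[i] = 1;
            ++removed_fluid[k];
          }
          break;
        }
      }
      // 6. adaptive controller: dP = h |rho - rho_t| / rho_t
      long cnt = 0;
      for (int i = 0; i < nReal; ++i)
        if (!dead[i] && reg[i] == 1 && spc[i] != WALL && !is_slaved_particle(i))
          ++cnt;
      double rho = (double)cnt / Vmain;
      rho_hist.push_back(rho);
      if ((int)rho_hist.size() > smooth_win) rho_hist.pop_front();
      double rho_s = 0;
      for (double v : rho_hist) rho_s += v;
      rho_s /= rho_hist.size();
      log_rho.push_back(rho);
      log_rho_smooth.push_back(rho_s);
      for (size_t k = 0; k < outlets.size(); ++k) {
        double dP = h * std::fabs(rho_s - outlets[k].rho_target) / outlets[k].rho_target;
        if (rho_s <= outlets[k].rho_target) outlets[k].P += dP;
        else outlets[k].P -= dP;
        if (outlets[k].P < 0) outlets[k].P = 0;
        if (outlets[k].P > 1) outlets[k].P = 1;
        log_P.push_back(outlets[k].P);
      }
    }

    // 7. compact dead particles (stable, remaps cell vertex offsets)
    bool any_dead = false;
    for (int i = 0; i < nReal; ++i) if (dead[i]) { any_dead = true; break; }
    if (any_dead) {
      std::vector<int> newidx(nReal, -1);
      int m = 0;
      for (int i = 0; i < nReal; ++i) {
        if (dead[i]) continue;
        newidx[i] = m;
        if (m != i) {
          for (int c = 0; c < 3; ++c) {
            pos[3 * m + c] = pos[3 * i + c];
            vel[3 * m + c] = vel[3 * i + c];
            frc[3 * m + c] = frc[3 * i + c];
          }
          spc[m] = spc[i]; reg[m] = reg[i]; cel[m] = cel[i];
        }
        ++m;
      }
      for (auto& C : cells)
        if (C.alive) C.first = newidx[C.first];
      nReal = m;
      pos.resize(3 * m); vel.resize(3 * m); frc.resize(3 * m);
      spc.resize(m); reg.resize(m); cel.resize(m); vir.resize(m);
    }

    if (obc) {
      // 8. materialize copy-border duplications
      for (size_t k = 0; k + 5 < dup_fluid.size(); k += 6) {
        pos.insert(pos.end(), {dup_fluid[k], dup_fluid[k + 1], dup_fluid[k + 2]});
        vel.insert(vel.end(), {dup_fluid[k + 3], dup_fluid[k + 4], dup_fluid[k + 5]});
        frc.insert(frc.end(), {0, 0, 0});
        spc.push_back(FLUID); reg.push_back(1); cel.push_back(-1);
        vir.push_back(0);
        ++nReal;
        ++inserted_fluid;
      }
      for (int ic : dup_cells) {
        Cell C = cells[ic]; // copy of the (already wrapped) original
        Cell D;
        D.nv = C.nv; D.tmpl = C.tmpl; D.reg = 1; D.A0 = C.A0; D.V0 = C.V0;
        D.slaved = 1; D.master = ic; D.offz = Lg; D.alive = 1;
        D.first = nReal;
        for (int v = 0; v < C.nv; ++v) {
          int src = C.first + v;
          pos.insert(pos.end(), {pos[3 * src], pos[3 * src + 1],
                                 pos[3 * src + 2] + Lg});
          vel.insert(vel.end(), {vel[3 * src], vel[3 * src + 1], vel[3 * src + 2]});
          frc.insert(frc.end(), {0, 0, 0});
          spc.push_back(MEMB); reg.push_back(1);
          cel.push_back((int)cells.size());
          vir.push_back(0);
          ++nReal;
        }
        cells.push_back(D);
        ++inserted_cells;
      }
      // 9. slaved duplicates mirror their originals exactly; release when the
      //    whole duplicate lies strictly inside the main domain
      for (size_t ic = 0; ic < cells.size(); ++ic) {
        Cell& D = cells[ic];
        if (!D.alive || !D.slaved) continue;
        const Cell& Mst = cells[D.master];
        bool inside = true;
        for (int v = 0; v < D.nv; ++v) {
          int dv = D.first + v, sv = Mst.first + v;
          pos[3 * dv] = pos[3 * sv];
          pos[3 * dv + 1] = pos[3 * sv + 1];
          pos[3 * dv + 2] = pos[3 * sv + 2] + D.offz;
          vel[3 * dv] = vel[3 * sv];
          vel[3 * dv + 1] = vel[3 * sv + 1];
          vel[3 * dv + 2] = vel[3 * sv + 2];
          if (pos[3 * dv + 2] <= Lg) inside = false;
        }
        if (inside) D.slaved = 0;
      }
      // 10. ghost regeneration for the generating region's periodicity
      for (int i = 0; i < nReal; ++i) {
        if (reg[i] != 0) continue;
        double z = pos[3 * i + 2];
        double zn;
        if (z < zone_w) zn = z + Lg;
        else if (z > Lg - zone_w) zn = z - Lg;
        else continue;
        pos.insert(pos.end(), {pos[3 * i], pos[3 * i + 1], zn});
        vel.insert(vel.end(), {vel[3 * i], vel[3 * i + 1], vel[3 * i + 2]});
        frc.insert(frc.end(), {0, 0, 0});
        spc.push_back(spc[i]); reg.push_back(9); cel.push_back(cel[i]);
        vir.push_back(0);
      }
    }

    // 11. forces at the new positions, then the trailing half kick
    compute_forces();
    for (int i = 0; i < nReal; ++i)
      if (integrable(i))
        for (int c = 0; c < 3; ++c) vel[3 * i + c] += 0.5 * dt * frc[3 * i + c] / mass;

    ++step_idx;
    check_cells();
    if (sample) take_sample();
  }

  // invariant check: every alive cell's vertex block is tagged with its own
  // cell index and membrane species
  void check_cells() const {
    for (size_t ic = 0; ic < cells.size(); ++ic) {
      const Cell& C = cells[ic];
      if (!C.alive) continue;
      if (C.first < 0 || C.first + C.nv > nReal)
        stop("cell %d vertex block out of range at step %ld", (int)ic + 1,
             step_idx);
      for (int v = 0; v < C.nv; ++v)
        if (cel[C.first + v] != (int)ic || spc[C.first + v] != MEMB)
          stop("cell table corrupted at step %ld (cell %d, vertex %d: cel=%d spc=%d)",
               step_idx, (int)ic + 1, v + 1, cel[C.first + v], spc[C.first + v]);
    }
  }

  void take_sample() {
    sample_steps.push_back((double)step_idx);
    // radial axial-velocity profile
    if (vel_nbins > 0) {
      std::vector<double> s(vel_nbins, 0.0), c(vel_nbins, 0.0);
      for (int i = 0; i < nReal; ++i) {
        if (spc[i] == WALL || reg[i] == 9 || is_slaved_particle(i)) continue;
        double z = pos[3 * i + 2];
        if (z < vel_zmin || z > vel_zmax) continue;
        double r = std::sqrt(pos[3 * i] * pos[3 * i] + pos[3 * i + 1] * pos[3 * i + 1]);
        int b = (int)std::floor(r / vel_rmax * vel_nbins);
        if (b < 0 || b >= vel_nbins) continue;
        s[b] += vel[3 * i + 2];
        c[b] += 1;
      }
      for (int b = 0; b < vel_nbins; ++b) {
        prof_sum.push_back(c[b] > 0 ? s[b] / c[b] : NA_REAL);
        prof_cnt.push_back(c[b]);
      }
    }
    // axial pressure profile from the per-particle virial
    if (pres_nslabs > 0) {
      std::vector<double> um(3 * pres_nslabs, 0.0), cn(pres_nslabs, 0.0);
      std::vector<double> kin(pres_nslabs, 0.0), vv(pres_nslabs, 0.0);
      double dz = (pres_zmax - pres_zmin) / pres_nslabs;
      auto slab = [&](int i) {
        if (spc[i] == WALL || reg[i] == 9 || is_slaved_particle(i)) return -1;
        double z = pos[3 * i + 2];
        if (z < pres_zmin || z >= pres_zmax) return -1;
        return (int)((z - pres_zmin) / dz);
      };
      for (int i = 0; i < nReal; ++i) {
        int b = slab(i);
        if (b < 0) continue;
        for (int c = 0; c < 3; ++c) um[3 * b + c] += vel[3 * i + c];
        cn[b] += 1;
      }
      for (int b = 0; b < pres_nslabs; ++b)
        if (cn[b] > 0)
          for (int c = 0; c < 3; ++c) um[3 * b + c] /= cn[b];
      for (int i = 0; i < nReal; ++i) {
        int b = slab(i);
        if (b < 0) continue;
        double pv = 0;
        for (int c = 0; c < 3; ++c) {
          double dvc = vel[3 * i + c] - um[3 * b + c];
          pv += dvc * dvc;
        }
        kin[b] += mass * pv / 3.0;
        vv[b] += vir[i];
      }
      for (int b = 0; b < pres_nslabs; ++b)
        pres_rows.push_back(cn[b] > 0 ? (kin[b] + vv[b]) / slab_vol : NA_REAL);
    }
    // kinetic temperature of the fluid, total momentum, main-domain count
    double ke = 0; long nf = 0;
    double mom[3] = {0, 0, 0};
    long cmain = 0;
    for (int i = 0; i < nReal; ++i) {
      if (reg[i] == 9) continue;
      if (spc[i] == FLUID && !is_slaved_particle(i)) {
        ke += 0.5 * mass * (vel[3 * i] * vel[3 * i] + vel[3 * i + 1] * vel[3 * i + 1] +
                            vel[3 * i + 2] * vel[3 * i + 2]);
        ++nf;
      }
      if (integrable(i))
        for (int c = 0; c < 3; ++c) mom[c] += mass * vel[3 * i + c];
      if (reg[i] == 1 && spc[i] != WALL && !is_slaved_particle(i)) ++cmain;
    }
    temp_rows.push_back(nf > 0 ? ke / nf : NA_REAL);
    for (int c = 0; c < 3; ++c) mom_rows.push_back(mom[c]);
    count_rows.push_back((double)cmain);
  }
};

// ---------------- R interface ----------------

static Geom geom_from_list(const List& g) {
  Geom G;
  G.type = as<int>(g["type"]);
  if (G.type == 1) G.R = as<double>(g["radius"]);
  if (G.type == 2) {
    G.Rp = as<double>(g["parent_radius"]);
    G.zj = as<double>(g["junction_z"]);
    NumericVector a1 = g["dir1"], a2 = g["dir2"], rd = g["daughter_radius"],
                  ld = g["daughter_length"];
    for (int c = 0; c < 3; ++c) { G.d1[c] = a1[c]; G.d2[c] = a2[c]; }
    G.Rd[0] = rd[0]; G.Rd[1] = rd[1];
    G.Ld[0] = ld[0]; G.Ld[1] = ld[1];
  }
  return G;
}

// [[Rcpp::export]]
SEXP cpp_sim_create(List state, List config) {
  Sim* S = new Sim();
  NumericMatrix P = state["position"], V = state["velocity"];
  IntegerVector sp = state["species"], rg = state["region"], cl = state["cell_id"];
  int n = P.nrow();
  S->nReal = n;
  S->pos.resize(3 * n); S->vel.resize(3 * n); S->frc.assign(3 * n, 0.0);
  S->vir.assign(n, 0.0);
  S->spc.resize(n); S->reg.resize(n); S->cel.resize(n);
  bool have_force = state.containsElementNamed("force") &&
                    !Rf_isNull(state["force"]);
  NumericMatrix F0 = have_force ? NumericMatrix(state["force"])
                                : NumericMatrix(1, 1);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) {
      S->pos[3 * i + c] = P(i, c);
      S->vel[3 * i + c] = V(i, c);
      if (have_force) S->frc[3 * i + c] = F0(i, c);
    }
    S->spc[i] = sp[i];
    S->reg[i] = rg[i];
    S->cel[i] = cl[i] == NA_INTEGER ? -1 : cl[i] - 1;
  }
  if (state.containsElementNamed("cells") && !Rf_isNull(state["cells"])) {
    List cs = state["cells"];
    IntegerVector first = cs["first"], nv = cs["nv"], tmpl = cs["template"],
                  creg = cs["region"], mast = cs["master"];
    NumericVector A0 = cs["A0"], V0 = cs["V0"], offz = cs["offz"];
    IntegerVector slv = cs["slaved"], alv = cs["alive"];
    for (int k = 0; k < first.size(); ++k) {
      Sim::Cell C;
      C.first = first[k] - 1; C.nv = nv[k]; C.tmpl = tmpl[k] - 1;
      C.reg = creg[k]; C.A0 = A0[k]; C.V0 = V0[k];
      C.slaved = (char)slv[k]; C.alive = (char)alv[k];
      C.master = mast[k] == NA_INTEGER ? -1 : mast[k] - 1;
      C.offz = offz[k];
      if (cs.containsElementNamed("latch")) {
        IntegerVector lt = cs["latch"];
        C.latch = (char)lt[k];
      }
      S->cells.push_back(C);
    }
  }
  if (config.containsElementNamed("templates") && !Rf_isNull(config["templates"])) {
    List ts = config["templates"];
    for (int k = 0; k < ts.size(); ++k) {
      List m = ts[k];
      MeshT M;
      M.nv = as<int>(m["nv"]);
      M.l0 = as<double>(m["l0"]);
      M.lm = as<double>(m["lm"]);
      IntegerMatrix spr = m["springs"], tri = m["triangles"], dih = m["dihedrals"];
      for (int r = 0; r < spr.nrow(); ++r) {
        M.springs.push_back(spr(r, 0) - 1);
        M.springs.push_back(spr(r, 1) - 1);
      }
      for (int r = 0; r < tri.nrow(); ++r)
        for (int c = 0; c < 3; ++c) M.triangles.push_back(tri(r, c) - 1);
      for (int r = 0; r < dih.nrow(); ++r)
        for (int c = 0; c < 4; ++c) M.dihedrals.push_back(dih(r, c) - 1);
      S->templates.push_back(M);
    }
  }

  List fl = config["fluid"];
  S->fp.a = as<double>(fl["a"]);
  S->fp.gamma = as<double>(fl["gamma"]);
  S->fp.rc = as<double>(fl["r_c"]);
  S->fp.kBT = as<double>(fl["kBT"]);
  S->fp.s = as<double>(fl["s"]);
  S->fp.n = as<double>(fl["n"]);
  S->fp.g = as<double>(fl["g"]);
  if (config.containsElementNamed("membrane") && !Rf_isNull(config["membrane"])) {
    List mb = config["membrane"];
    S->mp.p = as<double>(mb["p"]);
    S->mp.kb = as<double>(mb["k_b"]);
    S->mp.theta0 = as<double>(mb["theta0"]);
    S->mp.ka = as<double>(mb["k_a"]);
    S->mp.kv = as<double>(mb["k_v"]);
    S->mp.gT = as<double>(mb["gamma_T"]);
    S->mp.gC = as<double>(mb["gamma_C"]);
    S->mp.kBT = as<double>(mb["kBT"]);
  }
  S->geom = geom_from_list(config["geometry"]);
  S->dt = as<double>(config["dt"]);
  NumericVector bx = config["box"];
  for (int c = 0; c < 6; ++c) S->box[c] = bx[c];
  LogicalVector pp = config["periodic"];
  for (int c = 0; c < 3; ++c) S->per[c] = pp[c];
  S->therm = as<bool>(config["thermostat"]);
  S->limit_disp = config.containsElementNamed("limit_disp")
                      ? as<double>(config["limit_disp"]) : 0.0;
  if (config.containsElementNamed("gfactors")) {
    NumericVector gf = config["gfactors"];
    for (int c = 0; c < std::min(3, (int)gf.size()); ++c) S->gfac[c] = gf[c];
  }
  if (config.containsElementNamed("g_main_factor"))
    S->gmain = as<double>(config["g_main_factor"]);

  if (config.containsElementNamed("obc") && !Rf_isNull(config["obc"])) {
    List ob = config["obc"];
    S->obc = as<bool>(ob["enabled"]);
    if (S->obc) {
      S->Lg = as<double>(ob["generating_length"]);
      S->zone_w = as<double>(ob["zone_width"]);
      if (S->Lg < 2.0 * S->zone_w)
        stop("generating-region length must be at least twice the ghost-zone width");
      S->h = as<double>(ob["h"]);
      S->smooth_win = as<int>(ob["smooth_window"]);
      S->Vmain = as<double>(ob["main_volume"]);
      List outs = ob["outlets"];
      double P0 = as<double>(ob["P0"]);
      for (int k = 0; k < outs.size(); ++k) {
        List o = outs[k];
        Outlet O;
        NumericVector oo = o["origin"], dd = o["dir"];
        for (int c = 0; c < 3; ++c) { O.o[c] = oo[c]; O.dir[c] = dd[c]; }
        O.Ldel = as<double>(o["deletion_length"]);
        O.rho_target = as<double>(o["rho_target"]);
        if (O.rho_target <= 0) stop("rho_target must be positive");
        O.P = P0;
        S->outlets.push_back(O);
        S->outlet_branch.push_back(o.containsElementNamed("branch")
                                       ? as<int>(o["branch"]) : 0);
        S->removed_fluid.push_back(0);
      }
    }
  }

  // stats configuration
  if (config.containsElementNamed("stats") && !Rf_isNull(config["stats"])) {
    List st = config["stats"];
    S->vel_nbins = as<int>(st["vel_nbins"]);
    if (S->vel_nbins > 0) {
      S->vel_zmin = as<double>(st["vel_zmin"]);
      S->vel_zmax = as<double>(st["vel_zmax"]);
      S->vel_rmax = as<double>(st["vel_rmax"]);
    }
    S->pres_nslabs = as<int>(st["pres_nslabs"]);
    if (S->pres_nslabs > 0) {
      S->pres_zmin = as<double>(st["pres_zmin"]);
      S->pres_zmax = as<double>(st["pres_zmax"]);
      S->slab_vol = as<double>(st["slab_volume"]);
    }
  }

  // independent RNG streams per subsystem
  std::uint64_t master = (std::uint64_t)as<double>(config["seed"]);
  std::uint64_t sm = master;
  S->rng_fluid.seed(splitmix64(sm));
  S->rng_memb.seed(splitmix64(sm));
  S->rng_out.seed(splitmix64(sm));
  if (state.containsElementNamed("rng") && !Rf_isNull(state["rng"])) {
    CharacterVector rs = state["rng"];
    std::istringstream(std::string(rs[0])) >> S->rng_fluid;
    std::istringstream(std::string(rs[1])) >> S->rng_memb;
    std::istringstream(std::string(rs[2])) >> S->rng_out;
  }

  // a checkpointed state carries the forces of its last step (and the RNG
  // stream states), so restarting reproduces the trajectory bitwise; fresh
  // states need an initial force evaluation
  if (!have_force) S->compute_forces();
  XPtr<Sim> ptr(S, true);
  return ptr;
}

// [[Rcpp::export]]
void cpp_sim_run(SEXP simptr, int nsteps, int sample_every) {
  XPtr<Sim> S(simptr);
  for (int k = 0; k < nsteps; ++k) {
    bool sample = sample_every > 0 && ((S->step_idx + 1) % sample_every == 0);
    S->step(sample);
    if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
  }
}

// [[Rcpp::export]]
List cpp_sim_state(SEXP simptr) {
  XPtr<Sim> S(simptr);
  int n = S->nReal;
  NumericMatrix P(n, 3), V(n, 3), Fm(n, 3);
  IntegerVector sp(n), rg(n), cl(n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) {
      P(i, c) = S->pos[3 * i + c];
      V(i, c) = S->vel[3 * i + c];
      Fm(i, c) = S->frc[3 * i + c];
    }
    sp[i] = S->spc[i];
    rg[i] = S->reg[i];
    cl[i] = S->cel[i] < 0 ? NA_INTEGER : S->cel[i] + 1;
  }
  int nc = (int)S->cells.size();
  IntegerVector first(nc), nv(nc), tmpl(nc), creg(nc), mast(nc), slv(nc),
      alv(nc), ltc(nc);
  NumericVector A0(nc), V0(nc), offz(nc);
  for (int k = 0; k < nc; ++k) {
    const Sim::Cell& C = S->cells[k];
    first[k] = C.first + 1; nv[k] = C.nv; tmpl[k] = C.tmpl + 1;
    creg[k] = C.reg; mast[k] = C.master < 0 ? NA_INTEGER : C.master + 1;
    slv[k] = C.slaved; alv[k] = C.alive; A0[k] = C.A0; V0[k] = C.V0;
    offz[k] = C.offz; ltc[k] = C.latch;
  }
  std::ostringstream r1, r2, r3;
  r1 << S->rng_fluid; r2 << S->rng_memb; r3 << S->rng_out;
  return List::create(
      _["position"] = P, _["velocity"] = V, _["force"] = Fm,
      _["species"] = sp, _["region"] = rg, _["cell_id"] = cl,
      _["cells"] = List::create(_["first"] = first, _["nv"] = nv,
                                _["template"] = tmpl, _["region"] = creg,
                                _["A0"] = A0, _["V0"] = V0, _["slaved"] = slv,
                                _["master"] = mast, _["offz"] = offz,
                                _["alive"] = alv, _["latch"] = ltc),
      _["step"] = (double)S->step_idx,
      _["rng"] = CharacterVector::create(r1.str(), r2.str(), r3.str()));
}

// [[Rcpp::export]]
List cpp_sim_stats(SEXP simptr) {
  XPtr<Sim> S(simptr);
  int ns = (int)S->sample_steps.size();
  int nout = (int)S->outlets.size();
  NumericMatrix prof(ns, std::max(1, S->vel_nbins)),
      cnts(ns, std::max(1, S->vel_nbins)),
      pres(ns, std::max(1, S->pres_nslabs)), mom(ns, 3);
  if (S->vel_nbins > 0)
    for (int r = 0; r < ns; ++r)
      for (int b = 0; b < S->vel_nbins; ++b) {
        prof(r, b) = S->prof_sum[(size_t)r * S->vel_nbins + b];
        cnts(r, b) = S->prof_cnt[(size_t)r * S->vel_nbins + b];
      }
  if (S->pres_nslabs > 0)
    for (int r = 0; r < ns; ++r)
      for (int b = 0; b < S->pres_nslabs; ++b)
        pres(r, b) = S->pres_rows[(size_t)r * S->pres_nslabs + b];
  for (int r = 0; r < ns; ++r)
    for (int c = 0; c < 3; ++c) mom(r, c) = S->mom_rows[3 * r + c];
  int nexit = (int)S->exits.size() / 4;
  NumericMatrix ex(nexit, 4);
  for (int k = 0; k < nexit; ++k)
    for (int c = 0; c < 4; ++c) ex(k, c) = S->exits[4 * k + c];
  colnames(ex) = CharacterVector::create("step", "outlet", "cell", "nv");
  int nlog = (int)S->log_rho.size();
  NumericMatrix Pmat(nout > 0 ? nlog : 0, std::max(1, nout));
  for (int r = 0; r < (nout > 0 ? nlog : 0); ++r)
    for (int k = 0; k < nout; ++k) Pmat(r, k) = S->log_P[(size_t)r * nout + k];
  NumericVector rem(nout);
  for (int k = 0; k < nout; ++k) rem[k] = (double)S->removed_fluid[k];
  return List::create(
      _["sample_steps"] = NumericVector(S->sample_steps.begin(), S->sample_steps.end()),
      _["profile"] = prof, _["profile_counts"] = cnts, _["pressure"] = pres,
      _["temperature"] = NumericVector(S->temp_rows.begin(), S->temp_rows.end()),
      _["momentum"] = mom,
      _["main_count"] = NumericVector(S->count_rows.begin(), S->count_rows.end()),
      _["rho"] = NumericVector(S->log_rho.begin(), S->log_rho.end()),
      _["rho_smooth"] = NumericVector(S->log_rho_smooth.begin(), S->log_rho_smooth.end()),
      _["P"] = Pmat, _["removed_fluid"] = rem,
      _["removed_upstream"] = (double)S->removed_upstream,
      _["inserted_fluid"] = (double)S->inserted_fluid,
      _["inserted_cells"] = (double)S->inserted_cells,
      _["wall_clamp_warnings"] = (double)S->wall_clamp_warnings,
      _["exits"] = ex);
}

// [[Rcpp::export]]
void cpp_sim_reset_stats(SEXP simptr) {
  XPtr<Sim> S(simptr);
  S->prof_sum.clear(); S->prof_cnt.clear(); S->pres_rows.clear();
  S->temp_rows.clear(); S->mom_rows.clear(); S->count_rows.clear();
  S->sample_steps.clear(); S->log_rho.clear(); S->log_rho_smooth.clear();
  S->log_P.clear(); S->exits.clear();
  std::fill(S->removed_fluid.begin(), S->removed_fluid.end(), 0);
  S->inserted_fluid = 0; S->inserted_cells = 0; S->removed_upstream = 0;
}

// [[Rcpp::export]]
NumericVector cpp_sdf_many(List geometry, NumericMatrix points) {
  Geom G = geom_from_list(geometry);
  int n = points.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    out[i] = G.sdf(p);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_branch_many(List geometry, NumericMatrix points) {
  Geom G = geom_from_list(geometry);
  int n = points.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    out[i] = G.branch(p);
  }
  return out;
}
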