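// Membrane (triangulated red-blood-cell) force kernels and the generic
// cell-list neighbor search. Forces are exact negative gradients of the
// energies; the test suite checks them against central differences.
#include "common.h"
using namespace Rcpp;

// Accumulate all bonded membrane forces for one cell laid out in `pos`
// (xyz interleaved, global indexing through vidx0 + local id).
// Returns energies Vs, Vb, Va, Vv and instantaneous A, V through `out`.
void membrane_bonded_forces(const double* pos, double* frc, int vidx0,
                            const MeshT& M, const MembPar& mp,
                            double A0, double V0,
                            bool do_elastic, bool do_bend, bool do_av,
                            double* out /* Vs Vb Va Vv A V */) {
  const int nspr = (int)M.springs.size() / 2;
  const int ntri = (int)M.triangles.size() / 3;
  const int ndih = (int)M.dihedrals.size() / 4;
  double Vs = 0, Vb = 0, Va = 0, Vv = 0;

  // --- springs (WLC attractive part of the elastic energy) ---
  if (do_elastic) {
    for (int sidx = 0; sidx < nspr; ++sidx) {
      int i = vidx0 + M.springs[2 * sidx];
      int j = vidx0 + M.springs[2 * sidx + 1];
      double d[3] = {pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                     pos[3 * i + 2] - pos[3 * j + 2]};
      double l = norm3(d);
      double x = l / M.lm;
      if (x >= 1.0)
        stop("membrane spring overextended (x = l/lm >= 1): reduce dt or increase lm");
      Vs += wlc_energy(x, mp.kBT, mp.p, M.lm);
      double f = -wlc_dVdl(x, mp.kBT, mp.p) / l; // force on i along d
      if (frc) {
        for (int c = 0; c < 3; ++c) {
          frc[3 * i + c] += f * d[c];
          frc[3 * j + c] -= f * d[c];
        }
      }
    }
  }

  // --- per-triangle terms: area repulsion C/A (elastic), global area/volume ---
  double A = 0, V = 0;
  if (do_elastic || do_av) {
    double x0 = M.l0 / M.lm;
    double Crep = tri_repulsion_C(x0, M.lm, mp.kBT, mp.p);
    // first pass: totals
    for (int t = 0; t < ntri; ++t) {
      int ia = vidx0 + M.triangles[3 * t];
      int ib = vidx0 + M.triangles[3 * t + 1];
      int ic = vidx0 + M.triangles[3 * t + 2];
      const double *pa = pos + 3 * ia, *pb = pos + 3 * ib, *pc = pos + 3 * ic;
      double ab[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
      double ac[3] = {pc[0] - pa[0], pc[1] - pa[1], pc[2] - pa[2]};
      double nrm[3];
      cross3(ab, ac, nrm);
      double Atri = 0.5 * norm3(nrm);
      if (Atri <= 1e-14) stop("degenerate (zero-area) membrane triangle");
      A += Atri;
      double bc[3];
      cross3(pb, pc, bc);
      V += dot3(pa, bc) / 6.0;
      if (do_elastic) Vs += Crep / Atri;
    }
    if (do_av && V <= 0) stop("inverted membrane mesh (signed volume <= 0)");
    if (do_av) {
      Va = mp.ka * mp.kBT * (A - A0) * (A - A0) / (2.0 * M.l0 * M.l0 * A0);
      Vv = mp.kv * mp.kBT * (V - V0) * (V - V0) / (2.0 * M.l0 * M.l0 * M.l0 * V0);
    }
    // second pass: gradients
    if (frc) {
      double dVa_dA = do_av ? mp.ka * mp.kBT * (A - A0) / (M.l0 * M.l0 * A0) : 0.0;
      double dVv_dV = do_av ? mp.kv * mp.kBT * (V - V0) / (M.l0 * M.l0 * M.l0 * V0) : 0.0;
      for (int t = 0; t < ntri; ++t) {
        int ia = vidx0 + M.triangles[3 * t];
        int ib = vidx0 + M.triangles[3 * t + 1];
        int ic = vidx0 + M.triangles[3 * t + 2];
        const double *pa = pos + 3 * ia, *pb = pos + 3 * ib, *pc = pos + 3 * ic;
        double ab[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
        double ac[3] = {pc[0] - pa[0], pc[1] - pa[1], pc[2] - pa[2]};
        double nrm[3];
        cross3(ab, ac, nrm);
        double twoA = norm3(nrm);
        double Atri = 0.5 * twoA;
        double nh[3] = {nrm[0] / twoA, nrm[1] / twoA, nrm[2] / twoA};
        // dA/dpa = ((pb - pc) x nh)/2, cyclic
        double eA[3] = {pb[0] - pc[0], pb[1] - pc[1], pb[2] - pc[2]};
        double eB[3] = {pc[0] - pa[0], pc[1] - pa[1], pc[2] - pa[2]};
        double eC[3] = {pa[0] - pb[0], pa[1] - pb[1], pa[2] - pb[2]};
        double gA[3], gB[3], gC[3];
        cross3(eA, nh, gA);
        cross3(eB, nh, gB);
        cross3(eC, nh, gC);
        double coefA = dVa_dA;
        if (do_elastic) coefA += -Crep / (Atri * Atri); // d(C/A)/dA
        for (int c = 0; c < 3; ++c) {
          frc[3 * ia + c] -= coefA * 0.5 * gA[c];
          frc[3 * ib + c] -= coefA * 0.5 * gB[c];
          frc[3 * ic + c] -= coefA * 0.5 * gC[c];
        }
        if (do_av) {
          // dV/dpa = (pb x pc)/6, cyclic
          double va[3], vb[3], vc[3];
          cross3(pb, pc, va);
          cross3(pc, pa, vb);
          cross3(pa, pb, vc);
          for (int c = 0; c < 3; ++c) {
            frc[3 * ia + c] -= dVv_dV * va[c] / 6.0;
            frc[3 * ib + c] -= dVv_dV * vb[c] / 6.0;
            frc[3 * ic + c] -= dVv_dV * vc[c] / 6.0;
          }
        }
      }
    }
  }

  // --- dihedral bending ---
  if (do_bend) {
    for (int q = 0; q < ndih; ++q) {
      int ii = vidx0 + M.dihedrals[4 * q];
      int jj = vidx0 + M.dihedrals[4 * q + 1];
      int kk = vidx0 + M.dihedrals[4 * q + 2];
      int ll = vidx0 + M.dihedrals[4 * q + 3];
      const double *pi = pos + 3 * ii, *pj = pos + 3 * jj;
      const double *pk = pos + 3 * kk, *pl = pos + 3 * ll;
      double e[3] = {pj[0] - pi[0], pj[1] - pi[1], pj[2] - pi[2]};
      double ei_k[3] = {pk[0] - pi[0], pk[1] - pi[1], pk[2] - pi[2]};
      double ej_l[3] = {pl[0] - pj[0], pl[1] - pj[1], pl[2] - pj[2]};
      double N1[3], N2[3];
      cross3(e, ei_k, N1);                  // normal of (i,j,k)
      double me[3] = {-e[0], -e[1], -e[2]};
      cross3(me, ej_l, N2);                 // normal of (j,i,l)
      double n1 = norm3(N1), n2 = norm3(N2);
      if (n1 <= 1e-14 || n2 <= 1e-14) stop("degenerate dihedral (zero-area wing)");
      double le = norm3(e);
      double cosq = dot3(N1, N2) / (n1 * n2);
      if (cosq > 1.0) cosq = 1.0;
      if (cosq < -1.0) cosq = -1.0;
      double cr[3];
      cross3(N1, N2, cr);
      // signed sine: positive for a convex (outward-bulging) hinge
      double sinq = dot3(cr, e) / (n1 * n2 * le);
      double theta = std::atan2(sinq, cosq);
      Vb += mp.kb * (1.0 - std::cos(theta - mp.theta0));
      if (frc) {
        double dEdth = mp.kb * std::sin(theta - mp.theta0);
        double c1 = -le / (n1 * n1), c2 = -le / (n2 * n2);
        double t1 = dot3(ei_k, e) / (le * le);
        double t2p[3] = {pl[0] - pi[0], pl[1] - pi[1], pl[2] - pi[2]};
        double t2 = dot3(t2p, e) / (le * le);
        double u1 = 1.0 - t1, u2 = 1.0 - t2;
        for (int c = 0; c < 3; ++c) {
          double Gk = c1 * N1[c];
          double Gl = c2 * N2[c];
          double Gi = -u1 * c1 * N1[c] - u2 * c2 * N2[c];
          double Gj = -t1 * c1 * N1[c] - t2 * c2 * N2[c];
          frc[3 * kk + c] -= dEdth * Gk;
          frc[3 * ll + c] -= dEdth * Gl;
          frc[3 * ii + c] -= dEdth * Gi;
          frc[3 * jj + c] -= dEdth * Gj;
        }
      }
    }
  }

  out[0] = Vs; out[1] = Vb; out[2] = Va; out[3] = Vv; out[4] = A; out[5] = V;
}

// Membrane viscous (dissipative) + random spring forces, Eqs. per-spring
// F^D = -gT v_ij - gC (v_ij . e_ij) e_ij, with the fluctuation-dissipation
// matched random force built from the traceless-symmetric Wiener increment.
void membrane_viscous_forces(const double* pos, const double* vel, double* frc,
                             int vidx0, const MeshT& M, const MembPar& mp,
                             double dt, std::mt19937_64* rng) {
  const int nspr = (int)M.springs.size() / 2;
  std::normal_distribution<double> N01(0.0, 1.0);
  const double ampS = std::sqrt(2.0 * mp.kBT) * std::sqrt(2.0 * mp.gT);
  const double trc = 3.0 * mp.gC - mp.gT;
  const double ampT = std::sqrt(2.0 * mp.kBT) * std::sqrt(trc > 0 ? trc : 0.0) / 3.0;
  const double sdt = std::sqrt(dt);
  for (int sidx = 0; sidx < nspr; ++sidx) {
    int i = vidx0 + M.springs[2 * sidx];
    int j = vidx0 + M.springs[2 * sidx + 1];
    double d[3] = {pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                   pos[3 * i + 2] - pos[3 * j + 2]};
    double l = norm3(d);
    double e[3] = {d[0] / l, d[1] / l, d[2] / l};
    double v[3] = {vel[3 * i] - vel[3 * j], vel[3 * i + 1] - vel[3 * j + 1],
                   vel[3 * i + 2] - vel[3 * j + 2]};
    double vdote = dot3(v, e);
    double F[3];
    for (int c = 0; c < 3; ++c) F[c] = -mp.gT * v[c] - mp.gC * vdote * e[c];
    if (rng) {
      double W[9];
      for (int c = 0; c < 9; ++c) W[c] = sdt * N01(*rng); // dW entries ~ N(0, dt)
      double tr = W[0] + W[4] + W[8];
      // tracefree symmetric part applied to e, plus trace term, all / dt
      double Se[3];
      for (int r = 0; r < 3; ++r) {
        double s0 = 0.5 * (W[3 * r + 0] + W[0 + r]);
        double s1 = 0.5 * (W[3 * r + 1] + W[3 + r]);
        double s2 = 0.5 * (W[3 * r + 2] + W[6 + r]);
        if (r == 0) s0 -= tr / 3.0;
        if (r == 1) s1 -= tr / 3.0;
        if (r == 2) s2 -= tr / 3.0;
        Se[r] = s0 * e[0] + s1 * e[1] + s2 * e[2];
      }
      for (int c = 0; c < 3; ++c) F[c] += (ampS * Se[c] + ampT * tr * e[c]) / dt;
    }
    for (int c = 0; c < 3; ++c) {
      frc[3 * i + c] += F[c];
      frc[3 * j + c] -= F[c];
    }
  }
}

static MeshT mesh_from_list(const List& mesh) {
  MeshT M;
  IntegerMatrix spr = mesh["springs"], tri = mesh["triangles"], dih = mesh["dihedrals"];
  M.nv = as<int>(mesh["nv"]);
  M.l0 = as<double>(mesh["l0"]);
  M.lm = as<double>(mesh["lm"]);
  M.springs.resize(2 * spr.nrow());
  for (int r = 0; r < spr.nrow(); ++r)
    for (int c = 0; c < 2; ++c) M.springs[2 * r + c] = spr(r, c) - 1;
  M.triangles.resize(3 * tri.nrow());
  for (int r = 0; r < tri.nrow(); ++r)
    for (int c = 0; c < 3; ++c) M.triangles[3 * r + c] = tri(r, c) - 1;
  M.dihedrals.resize(4 * dih.nrow());
  for (int r = 0; r < dih.nrow(); ++r)
    for (int c = 0; c < 4; ++c) M.dihedrals[4 * r + c] = dih(r, c) - 1;
  return M;
}

static MembPar membpar_from_list(const List& par) {
  MembPar mp;
  mp.p = as<double>(par["p"]);
  mp.kb = as<double>(par["k_b"]);
  mp.theta0 = as<double>(par["theta0"]);
  mp.ka = as<double>(par["k_a"]);
  mp.kv = as<double>(par["k_v"]);
  mp.gT = as<double>(par["gamma_T"]);
  mp.gC = as<double>(par["gamma_C"]);
  mp.kBT = as<double>(par["kBT"]);
  return mp;
}

// [[Rcpp::export]]
List cpp_membrane_forces(NumericMatrix positions, List mesh, List params,
                         double A0, double V0, bool elastic, bool bending,
                         bool area_volume) {
  MeshT M = mesh_from_list(mesh);
  MembPar mp = membpar_from_list(params);
  int nv = positions.nrow();
  std::vector<double> pos(3 * nv), frc(3 * nv, 0.0);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) pos[3 * i + c] = positions(i, c);
  double out[6];
  membrane_bonded_forces(pos.data(), frc.data(), 0, M, mp, A0, V0, elastic,
                         bending, area_volume, out);
  NumericMatrix F(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) F(i, c) = frc[3 * i + c];
  return List::create(_["forces"] = F, _["V_s"] = out[0], _["V_b"] = out[1],
                      _["V_a"] = out[2], _["V_v"] = out[3], _["area"] = out[4],
                      _["volume"] = out[5]);
}

// [[Rcpp::export]]
List cpp_membrane_viscous(NumericMatrix positions, NumericMatrix velocities,
                          List mesh, List params, double dt,
                          Nullable<NumericMatrix> dW = R_NilValue) {
  // With dW supplied (n_springs x 9 Wiener increments, variance dt entries)
  // the random force is computed from it; with dW = NULL only the
  // dissipative part is returned.
  MeshT M = mesh_from_list(mesh);
  MembPar mp = membpar_from_list(params);
  int nv = positions.nrow();
  std::vector<double> pos(3 * nv), vel(3 * nv), frc(3 * nv, 0.0);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) {
      pos[3 * i + c] = positions(i, c);
      vel[3 * i + c] = velocities(i, c);
    }
  membrane_viscous_forces(pos.data(), vel.data(), frc.data(), 0, M, mp, dt, nullptr);
  NumericMatrix Fd(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) Fd(i, c) = frc[3 * i + c];
  NumericMatrix Fr(nv, 3);
  if (dW.isNotNull()) {
    NumericMatrix W(dW);
    const double ampS = std::sqrt(2.0 * mp.kBT) * std::sqrt(2.0 * mp.gT);
    const double trc = 3.0 * mp.gC - mp.gT;
    const double ampT = std::sqrt(2.0 * mp.kBT) * std::sqrt(trc > 0 ? trc : 0.0) / 3.0;
    int nspr = (int)M.springs.size() / 2;
    for (int sidx = 0; sidx < nspr; ++sidx) {
      int i = M.springs[2 * sidx], j = M.springs[2 * sidx + 1];
      double d[3] = {pos[3 * i] - pos[3 * j], pos[3 * i + 1] - pos[3 * j + 1],
                     pos[3 * i + 2] - pos[3 * j + 2]};
      double l = norm3(d);
      double e[3] = {d[0] / l, d[1] / l, d[2] / l};
      double Wm[9];
      for (int c = 0; c < 9; ++c) Wm[c] = W(sidx, c);
      double tr = Wm[0] + Wm[4] + Wm[8];
      double F[3];
      for (int r = 0; r < 3; ++r) {
        double s0 = 0.5 * (Wm[3 * r + 0] + Wm[0 + r]);
        double s1 = 0.5 * (Wm[3 * r + 1] + Wm[3 + r]);
        double s2 = 0.5 * (Wm[3 * r + 2] + Wm[6 + r]);
        if (r == 0) s0 -= tr / 3.0;
        if (r == 1) s1 -= tr / 3.0;
        if (r == 2) s2 -= tr / 3.0;
        F[r] = (ampS * (s0 * e[0] + s1 * e[1] + s2 * e[2]) + ampT * tr * e[r]) / dt;
      }
      for (int c = 0; c < 3; ++c) {
        Fr(i, c) += F[c];
        Fr(j, c) -= F[c];
      }
    }
  }
  return List::create(_["dissipative"] = Fd, _["random"] = Fr);
}

// Uniform cell-list neighbor search; returns the unordered pairs with
// separation < cutoff (1-based indices), honoring minimum-image periodicity
// only in the flagged dimensions.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix positions, double cutoff,
                                 NumericVector box, LogicalVector periodic) {
  int n = positions.nrow();
  std::vector<std::pair<int, int>> pairs;
  double lo[3] = {box[0], box[2], box[4]};
  double hi[3] = {box[1], box[3], box[5]};
  double L[3], rc2 = cutoff * cutoff;
  int nb[3];
  for (int c = 0; c < 3; ++c) {
    L[c] = hi[c] - lo[c];
    if (periodic[c] && cutoff > 0.5 * L[c])
      stop("cutoff exceeds half the periodic box edge (minimum image violated)");
    nb[c] = std::max(1, (int)std::floor(L[c] / cutoff));
  }
  std::vector<int> head((size_t)nb[0] * nb[1] * nb[2], -1), nxt(n, -1);
  auto binof = [&](int i) {
    int b[3];
    for (int c = 0; c < 3; ++c) {
      double x = positions(i, c);
      if (periodic[c]) x = x - L[c] * std::floor((x - lo[c]) / L[c]);
      int k = (int)std::floor((x - lo[c]) / (L[c] / nb[c]));
      if (k < 0) k = 0;
      if (k >= nb[c]) k = nb[c] - 1;
      b[c] = k;
    }
    return (b[2] * nb[1] + b[1]) * nb[0] + b[0];
  };
  for (int i = 0; i < n; ++i) {
    int b = binof(i);
    nxt[i] = head[b];
    head[b] = i;
  }
  auto mind2 = [&](int i, int j) {
    double s = 0;
    for (int c = 0; c < 3; ++c) {
      double d = positions(i, c) - positions(j, c);
      if (periodic[c]) d -= L[c] * std::round(d / L[c]);
      s += d * d;
    }
    return s;
  };
  for (int bz = 0; bz < nb[2]; ++bz)
    for (int by = 0; by < nb[1]; ++by)
      for (int bx = 0; bx < nb[0]; ++bx) {
        int b = (bz * nb[1] + by) * nb[0] + bx;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int cx = bx + dx, cy = by + dy, cz = bz + dz;
              if (periodic[0]) cx = (cx + nb[0]) % nb[0];
              if (periodic[1]) cy = (cy + nb[1]) % nb[1];
              if (periodic[2]) cz = (cz + nb[2]) % nb[2];
              if (cx < 0 || cx >= nb[0] || cy < 0 || cy >= nb[1] || cz < 0 ||
                  cz >= nb[2])
                continue;
              int b2 = (cz * nb[1] + cy) * nb[0] + cx;
              if (b2 < b) continue;
              for (int i = head[b]; i >= 0; i = nxt[i])
                for (int j = (b2 == b) ? nxt[i] : head[b2]; j >= 0; j = nxt[j]) {
                  if (b2 == b && j >= i) { if (j == i) continue; }
                  if (mind2(i, j) < rc2) {
                    int lo_ = std::min(i, j), hi_ = std::max(i, j);
                    pairs.emplace_back(lo_, hi_);
                  }
                }
            }
      }
  // de-duplicate (small-box periodic cases can visit a pair twice)
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  IntegerMatrix out((int)pairs.size(), 2);
  for (int k = 0; k < (int)pairs.size(); ++k) {
    out(k, 0) = pairs[k].first + 1;
    out(k, 1) = pairs[k].second + 1;
  }
  return out;
}
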