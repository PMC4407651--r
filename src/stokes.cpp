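// Staggered (MAC) finite-difference Stokes solver for the homogenization
// cell problem on a voxel fluid mask.
//
//   -div(grad nu_k) + grad pi_k = e_k   in the fluid domain
//    div nu_k = 0,  nu_k = 0 on solid/air interfaces
//
// Outer boundaries: either mirror-symmetry conditions (the half-cell
// formulation: pressure and tangential velocity odd across faces normal to
// the driving direction, normal velocity odd across the other faces) or
// fully periodic (for the explicitly reflected geometry). Both routes give
// the same discrete solution on mirror-symmetric geometry.
//
// Linear algebra: pressure Schur-complement CG; each application solves
// three decoupled velocity Poisson systems by Jacobi-preconditioned CG.
// All lengths in voxel units; physical scaling is applied by the caller.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const int WALL1 = -1;  // Dirichlet zero at distance h   (adds 1 to diagonal)
const int WALL2 = -2;  // wall at h/2, ghost = -u        (adds 2 to diagonal)
const int NONE  = -3;  // symmetry ghost = +u            (no contribution)

struct CompGrid {
  int m[3];                  // face-grid dimensions
  std::vector<int> actid;    // face -> unknown id or -1
  std::vector<R_xlen_t> face;// unknown -> face linear index
  std::vector<int> nbr;      // 6 codes per unknown
  std::vector<double> diag;  // Laplacian diagonal (unweighted)
  std::vector<double> wgt;   // row weight (0.5 on driving-direction planes)
  int nun = 0;
};

struct Problem {
  int n[3];
  int k;        // driving direction 0..2
  int mode;     // 0 = symmetric, 1 = periodic
  const int* fluid;
  CompGrid g[3];
  std::vector<int> pid;        // cell -> pressure unknown id or -1
  std::vector<R_xlen_t> pcell; // pressure unknown -> cell index
  int np = 0;
};

inline R_xlen_t lin(const int* d, int i, int j, int k) {
  return i + (R_xlen_t)d[0] * (j + (R_xlen_t)d[1] * k);
}

// resolve a cell coordinate that may be out of range by one
inline int rcell(int x, int n, int mode) {
  if (x < 0)  return mode == 1 ? n - 1 : 0;
  if (x >= n) return mode == 1 ? 0 : n - 1;
  return x;
}

inline bool cell_fluid(const Problem& P, int x, int y, int z) {
  int c[3] = {rcell(x, P.n[0], P.mode), rcell(y, P.n[1], P.mode),
              rcell(z, P.n[2], P.mode)};
  return P.fluid[lin(P.n, c[0], c[1], c[2])] != 0;
}

void build_comp(Problem& P, int c) {
  CompGrid& G = P.g[c];
  for (int a = 0; a < 3; ++a)
    G.m[a] = P.n[a] + ((a == c && P.mode == 0) ? 1 : 0);
  R_xlen_t M = (R_xlen_t)G.m[0] * G.m[1] * G.m[2];
  G.actid.assign(M, -1);
  // pass 1: activity
  int f[3];
  for (f[2] = 0; f[2] < G.m[2]; ++f[2])
    for (f[1] = 0; f[1] < G.m[1]; ++f[1])
      for (f[0] = 0; f[0] < G.m[0]; ++f[0]) {
        if (P.mode == 0 && c != P.k && (f[c] == 0 || f[c] == P.n[c]))
          continue;  // zero normal flow through symmetry planes
        int cm[3] = {f[0], f[1], f[2]}; cm[c] -= 1;
        if (!cell_fluid(P, cm[0], cm[1], cm[2])) continue;
        if (!cell_fluid(P, f[0], f[1], f[2])) continue;
        R_xlen_t q = lin(G.m, f[0], f[1], f[2]);
        G.actid[q] = G.nun++;
        G.face.push_back(q);
      }
  // pass 2: stencils
  G.nbr.assign((R_xlen_t)6 * G.nun, NONE);
  G.diag.assign(G.nun, 0.0);
  G.wgt.assign(G.nun, 1.0);
  for (int u = 0; u < G.nun; ++u) {
    R_xlen_t q = G.face[u];
    int k3 = q / ((R_xlen_t)G.m[0] * G.m[1]);
    R_xlen_t rem = q - (R_xlen_t)k3 * G.m[0] * G.m[1];
    int f0[3] = {(int)(rem % G.m[0]), (int)(rem / G.m[0]), k3};
    if (P.mode == 0 && c == P.k && (f0[c] == 0 || f0[c] == P.n[c]))
      G.wgt[u] = 0.5;  // half-faces on the driving-direction planes
    int slot = 0;
    for (int a = 0; a < 3; ++a)
      for (int s = -1; s <= 1; s += 2, ++slot) {
        int g[3] = {f0[0], f0[1], f0[2]};
        g[a] += s;
        int code;
        if (a == c) {
          // collinear neighbour (face-indexed axis)
          if (P.mode == 1) {
            if (g[a] < 0) g[a] = G.m[a] - 1;
            else if (g[a] >= G.m[a]) g[a] = 0;
          } else if (c == P.k) {
            if (g[a] < 0) g[a] = 1;
            else if (g[a] > P.n[c]) g[a] = P.n[c] - 1;
          }
          // c != k: endpoints 0..n exist in grid, inactive => WALL1
          code = G.actid[lin(G.m, g[0], g[1], g[2])];
          if (code >= 0) { G.nbr[6 * u + slot] = code; G.diag[u] += 1.0; }
          else           { G.nbr[6 * u + slot] = WALL1; G.diag[u] += 1.0; }
        } else {
          // transverse neighbour (cell-indexed axis)
          if (P.mode == 1) {
            if (g[a] < 0) g[a] = P.n[a] - 1;
            else if (g[a] >= P.n[a]) g[a] = 0;
          } else if (g[a] < 0 || g[a] >= P.n[a]) {
            if (a == P.k) { G.nbr[6 * u + slot] = WALL2; G.diag[u] += 2.0; }
            else          { G.nbr[6 * u + slot] = NONE; }
            continue;
          }
          code = G.actid[lin(G.m, g[0], g[1], g[2])];
          if (code >= 0) { G.nbr[6 * u + slot] = code; G.diag[u] += 1.0; }
          else {
            int cm[3] = {g[0], g[1], g[2]}; cm[c] -= 1;
            bool fm = cell_fluid(P, cm[0], cm[1], cm[2]);
            bool fp = cell_fluid(P, g[0], g[1], g[2]);
            if (!fm && !fp) { G.nbr[6 * u + slot] = WALL2; G.diag[u] += 2.0; }
            else            { G.nbr[6 * u + slot] = WALL1; G.diag[u] += 1.0; }
          }
        }
      }
  }
}

// y = A x (weighted vector Laplacian, one component)
void amul(const CompGrid& G, const std::vector<double>& x,
          std::vector<double>& y) {
  for (int u = 0; u < G.nun; ++u) {
    double acc = G.diag[u] * x[u];
    const int* nb = &G.nbr[(R_xlen_t)6 * u];
    for (int t = 0; t < 6; ++t)
      if (nb[t] >= 0) acc -= x[nb[t]];
    y[u] = G.wgt[u] * acc;
  }
}

// Jacobi-preconditioned CG for A x = b; returns iterations (-1 = no conv.)
int cg_comp(const CompGrid& G, const std::vector<double>& b,
            std::vector<double>& x, double rtol, int maxit) {
  int n = G.nun;
  x.assign(n, 0.0);
  double bb = 0;
  for (int i = 0; i < n; ++i) bb += b[i] * b[i];
  if (bb == 0) return 0;
  std::vector<double> r(b), z(n), p(n), Ap(n);
  std::vector<double> minv(n);
  for (int i = 0; i < n; ++i) minv[i] = 1.0 / (G.wgt[i] * G.diag[i]);
  double rz = 0;
  for (int i = 0; i < n; ++i) { z[i] = minv[i] * r[i]; rz += r[i] * z[i]; }
  p = z;
  double tol2 = rtol * rtol * bb;
  for (int it = 1; it <= maxit; ++it) {
    amul(G, p, Ap);
    double pAp = 0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0) return -1;
    double alpha = rz / pAp;
    double rr = 0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rr += r[i] * r[i];
    }
    if (rr < tol2) return it;
    double rznew = 0;
    for (int i = 0; i < n; ++i) { z[i] = minv[i] * r[i]; rznew += r[i] * z[i]; }
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
  return -1;
}

// divergence: q[cell] = sum_a u_a(upper) - u_a(lower), fluid cells only
void divergence(const Problem& P, const std::vector<double>* u,
                std::vector<double>& q) {
  std::fill(q.begin(), q.end(), 0.0);
  for (int ip = 0; ip < P.np; ++ip) {
    R_xlen_t cell = P.pcell[ip];
    int k3 = cell / ((R_xlen_t)P.n[0] * P.n[1]);
    R_xlen_t rem = cell - (R_xlen_t)k3 * P.n[0] * P.n[1];
    int c[3] = {(int)(rem % P.n[0]), (int)(rem / P.n[0]), k3};
    double acc = 0;
    for (int a = 0; a < 3; ++a) {
      const CompGrid& G = P.g[a];
      int lo[3] = {c[0], c[1], c[2]};
      int hi[3] = {c[0], c[1], c[2]};
      hi[a] += 1;
      if (P.mode == 1 && hi[a] >= P.n[a]) hi[a] = 0;
      int alo = G.actid[lin(G.m, lo[0], lo[1], lo[2])];
      int ahi = G.actid[lin(G.m, hi[0], hi[1], hi[2])];
      if (ahi >= 0) acc += u[a][ahi];
      if (alo >= 0) acc -= u[a][alo];
    }
    q[ip] = acc;
  }
}

// scatter transpose: y_a = D^T q
void divT(const Problem& P, const std::vector<double>& q,
          std::vector<double>* y) {
  for (int a = 0; a < 3; ++a) std::fill(y[a].begin(), y[a].end(), 0.0);
  for (int ip = 0; ip < P.np; ++ip) {
    R_xlen_t cell = P.pcell[ip];
    int k3 = cell / ((R_xlen_t)P.n[0] * P.n[1]);
    R_xlen_t rem = cell - (R_xlen_t)k3 * P.n[0] * P.n[1];
    int c[3] = {(int)(rem % P.n[0]), (int)(rem / P.n[0]), k3};
    for (int a = 0; a < 3; ++a) {
      const CompGrid& G = P.g[a];
      int lo[3] = {c[0], c[1], c[2]};
      int hi[3] = {c[0], c[1], c[2]};
      hi[a] += 1;
      if (P.mode == 1 && hi[a] >= P.n[a]) hi[a] = 0;
      int alo = G.actid[lin(G.m, lo[0], lo[1], lo[2])];
      int ahi = G.actid[lin(G.m, hi[0], hi[1], hi[2])];
      if (ahi >= 0) y[a][ahi] += q[ip];
      if (alo >= 0) y[a][alo] -= q[ip];
    }
  }
}

// Sparse 7-point pressure network operator L_p = D diag(A)^{-1} D^T
// (the SIMPLE approximation of the Schur complement): face conductances
// g_f = 1/(w_f diagA_f) between fluid-cell neighbours.
struct PressureNet {
  std::vector<int> ptr, col;
  std::vector<double> val, diag;
};

void lp_mul(const PressureNet& L, const std::vector<double>& x,
            std::vector<double>& y) {
  int n = (int)L.diag.size();
  for (int i = 0; i < n; ++i) {
    double acc = L.diag[i] * x[i];
    for (int t = L.ptr[i]; t < L.ptr[i + 1]; ++t)
      acc -= L.val[t] * x[L.col[t]];
    y[i] = acc;
  }
}

// a few Jacobi-CG sweeps on L_p z = r (approximate preconditioner solve)
void lp_solve(const PressureNet& L, const std::vector<double>& b,
              std::vector<double>& x, int maxit, double rtol) {
  int n = (int)L.diag.size();
  x.assign(n, 0.0);
  double bb = 0;
  for (int i = 0; i < n; ++i) bb += b[i] * b[i];
  if (bb == 0) return;
  std::vector<double> r(b), z(n), p(n), Ap(n);
  double rz = 0;
  for (int i = 0; i < n; ++i) { z[i] = r[i] / L.diag[i]; rz += r[i] * z[i]; }
  p = z;
  double tol2 = rtol * rtol * bb;
  for (int it = 0; it < maxit; ++it) {
    lp_mul(L, p, Ap);
    double pAp = 0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0) break;
    double alpha = rz / pAp;
    double rr = 0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rr += r[i] * r[i];
    }
    if (rr < tol2) break;
    double rznew = 0;
    for (int i = 0; i < n; ++i) { z[i] = r[i] / L.diag[i]; rznew += r[i] * z[i]; }
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
}

// subtract per-group means (pressure nullspace deflation)
void project(const std::vector<int>& grp, int ngrp, std::vector<double>& q) {
  if (ngrp == 0) return;
  std::vector<double> sum(ngrp + 1, 0.0);
  std::vector<double> cnt(ngrp + 1, 0.0);
  for (size_t i = 0; i < q.size(); ++i) {
    int g = grp[i];
    if (g > 0) { sum[g] += q[i]; cnt[g] += 1; }
  }
  for (int g = 1; g <= ngrp; ++g) if (cnt[g] > 0) sum[g] /= cnt[g];
  for (size_t i = 0; i < q.size(); ++i) {
    int g = grp[i];
    if (g > 0) q[i] -= sum[g];
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_stokes_solve(IntegerVector fluid, IntegerVector dim, int k, int mode,
                      double tol, int maxit_outer, int maxit_inner,
                      double tol_inner, IntegerVector proj_group,
                      bool want_fields) {
  Problem P;
  P.n[0] = dim[0]; P.n[1] = dim[1]; P.n[2] = dim[2];
  P.k = k; P.mode = mode;
  P.fluid = INTEGER(fluid);
  R_xlen_t N = (R_xlen_t)P.n[0] * P.n[1] * P.n[2];

  for (int c = 0; c < 3; ++c) build_comp(P, c);

  // pressure numbering + projection groups restricted to fluid cells
  P.pid.assign(N, -1);
  int ngrp = 0;
  std::vector<int> grp;
  for (R_xlen_t i = 0; i < N; ++i)
    if (P.fluid[i]) {
      P.pid[i] = P.np++;
      P.pcell.push_back(i);
      grp.push_back(proj_group[i]);
      ngrp = std::max(ngrp, proj_group[i]);
    }

  std::vector<double> u[3], rhs[3], w[3];
  for (int c = 0; c < 3; ++c) {
    u[c].assign(P.g[c].nun, 0.0);
    rhs[c].assign(P.g[c].nun, 0.0);
    w[c].assign(P.g[c].nun, 0.0);
  }
  List out;
  if (P.g[0].nun + P.g[1].nun + P.g[2].nun == 0 || P.np == 0) {
    out["mean_v"] = NumericVector::create(0, 0, 0);
    out["converged"] = true;
    out["iterations"] = 0;
    out["rel_residual"] = 0.0;
    out["div_inf"] = 0.0;
    out["mom_rel"] = 0.0;
    out["residual_history"] = NumericVector(0);
    out["n_unknowns"] = 0;
    return out;
  }

  // unit body force on driving-direction faces (weighted)
  for (int uix = 0; uix < P.g[k].nun; ++uix)
    rhs[k][uix] = P.g[k].wgt[uix];

  bool inner_fail = false;
  for (int c = 0; c < 3; ++c)
    if (cg_comp(P.g[c], rhs[c], u[c], tol_inner, maxit_inner) < 0)
      inner_fail = true;

  // Schur-complement flexible PCG:  S p = -D A^{-1} f,  S = D A^{-1} D^T.
  // Preconditioner: approximate solve of the SIMPLE surrogate
  // L_p = D diag(A)^{-1} D^T, the pressure network Laplacian. On
  // partially drained, film-dominated water domains S is dominated by
  // exactly this network coupling, so a surrogate solve removes the
  // long-wavelength pressure modes that stall plain CG. The surrogate is
  // applied inexactly (a capped CG), hence the flexible (Polak-Ribiere)
  // outer recurrence.
  PressureNet Lp;
  Lp.ptr.assign(P.np + 1, 0);
  Lp.diag.assign(P.np, 0.0);
  {
    std::vector<int> cols;
    std::vector<double> vals;
    for (int ip = 0; ip < P.np; ++ip) {
      R_xlen_t cell = P.pcell[ip];
      int k3 = cell / ((R_xlen_t)P.n[0] * P.n[1]);
      R_xlen_t rem = cell - (R_xlen_t)k3 * P.n[0] * P.n[1];
      int c[3] = {(int)(rem % P.n[0]), (int)(rem / P.n[0]), k3};
      for (int a = 0; a < 3; ++a)
        for (int s = -1; s <= 1; s += 2) {
          const CompGrid& G = P.g[a];
          // face between this cell and its neighbour in direction (a, s)
          int f[3] = {c[0], c[1], c[2]};
          if (s > 0) f[a] += 1;
          int nb[3] = {c[0], c[1], c[2]};
          nb[a] += s;
          bool open_end = false;  // symmetry plane normal to k: no neighbour
          if (P.mode == 1) {
            if (f[a] >= P.n[a]) f[a] = 0;
            nb[a] = rcell(nb[a], P.n[a], 1);
          } else if (nb[a] < 0 || nb[a] >= P.n[a]) {
            if (a != P.k) continue;  // closed symmetry plane, no flux
            open_end = true;
          }
          int af = G.actid[lin(G.m, f[0], f[1], f[2])];
          if (af < 0) continue;
          double g = 1.0 / (G.wgt[af] * G.diag[af]);
          Lp.diag[ip] += g;
          if (!open_end) {
            int jq = P.pid[lin(P.n, nb[0], nb[1], nb[2])];
            if (jq >= 0 && jq != ip) { cols.push_back(jq); vals.push_back(g); }
          }
        }
      Lp.ptr[ip + 1] = (int)cols.size();
      if (Lp.diag[ip] <= 0) Lp.diag[ip] = 1.0;
    }
    Lp.col = cols;
    Lp.val = vals;
  }
  std::vector<double> bp(P.np), r(P.np), z(P.np), d(P.np), Sd(P.np);
  divergence(P, u, bp);
  for (int i = 0; i < P.np; ++i) bp[i] = -bp[i];
  project(grp, ngrp, bp);
  double bnorm = 0;
  for (int i = 0; i < P.np; ++i) bnorm += bp[i] * bp[i];
  bnorm = std::sqrt(bnorm);

  std::vector<double> p(P.np, 0.0);
  std::vector<double> hist;
  double relres = 0.0;
  bool converged = true;
  int iters = 0;
  if (bnorm > 1e-300) {
    r = bp;
    std::vector<double> r_old(P.np, 0.0);
    lp_solve(Lp, r, z, 60, 1e-4);
    project(grp, ngrp, z);
    double rz = 0;
    for (int i = 0; i < P.np; ++i) rz += r[i] * z[i];
    d = z;
    converged = false;
    for (int it = 1; it <= maxit_outer; ++it) {
      iters = it;
      divT(P, d, w);
      std::vector<double> Aw[3];
      for (int c = 0; c < 3; ++c) {
        Aw[c].assign(P.g[c].nun, 0.0);
        if (cg_comp(P.g[c], w[c], Aw[c], tol_inner, maxit_inner) < 0)
          inner_fail = true;
      }
      divergence(P, Aw, Sd);
      project(grp, ngrp, Sd);
      double dSd = 0;
      for (int i = 0; i < P.np; ++i) dSd += d[i] * Sd[i];
      if (dSd <= 0) { converged = false; break; }
      double alpha = rz / dSd;
      double rrnew = 0;
      for (int i = 0; i < P.np; ++i) {
        p[i] += alpha * d[i];
        r_old[i] = r[i];
        r[i] -= alpha * Sd[i];
      }
      for (int c = 0; c < 3; ++c)
        for (int i = 0; i < P.g[c].nun; ++i) u[c][i] += alpha * Aw[c][i];
      project(grp, ngrp, r);
      for (int i = 0; i < P.np; ++i) rrnew += r[i] * r[i];
      relres = std::sqrt(rrnew) / bnorm;
      hist.push_back(relres);
      if (relres < tol) { converged = true; break; }
      lp_solve(Lp, r, z, 60, 1e-4);
      project(grp, ngrp, z);
      // flexible (Polak-Ribiere) recurrence: the preconditioner solve is
      // inexact, so use z'(r - r_old) rather than z'r
      double rznew = 0, rzflex = 0;
      for (int i = 0; i < P.np; ++i) {
        rznew += r[i] * z[i];
        rzflex += z[i] * (r[i] - r_old[i]);
      }
      double beta = rzflex / rz;
      if (!std::isfinite(beta) || beta < 0) beta = 0;
      rz = rznew;
      for (int i = 0; i < P.np; ++i) d[i] = z[i] + beta * d[i];
      if (it % 8 == 0) Rcpp::checkUserInterrupt();
    }
  }
  if (inner_fail) converged = false;

  // diagnostics: true divergence and momentum residual
  std::vector<double> dv(P.np);
  divergence(P, u, dv);
  double div_inf = 0;
  for (int i = 0; i < P.np; ++i) div_inf = std::max(div_inf, std::abs(dv[i]));
  divT(P, p, w);  // w = D^T p
  double mom2 = 0, f2 = 0;
  for (int c = 0; c < 3; ++c) {
    std::vector<double> Au(P.g[c].nun);
    amul(P.g[c], u[c], Au);
    for (int i = 0; i < P.g[c].nun; ++i) {
      double res = Au[i] - w[c][i] - rhs[c][i];
      mom2 += res * res;
      f2 += rhs[c][i] * rhs[c][i];
    }
  }
  double mom_rel = f2 > 0 ? std::sqrt(mom2 / f2) : 0.0;

  // cell-averaged velocity means over ALL cells (solid cells contribute 0).
  // In symmetric mode the average is taken over the full reflected cell:
  // components transverse to the driving direction are odd across their
  // mirror planes, so their full-cell average is identically zero.
  NumericVector mean_v(3);
  for (int a = 0; a < 3; ++a) {
    if (P.mode == 0 && a != P.k) { mean_v[a] = 0.0; continue; }
    const CompGrid& G = P.g[a];
    double acc = 0;
    for (int ip = 0; ip < P.np; ++ip) {
      R_xlen_t cell = P.pcell[ip];
      int k3 = cell / ((R_xlen_t)P.n[0] * P.n[1]);
      R_xlen_t rem = cell - (R_xlen_t)k3 * P.n[0] * P.n[1];
      int c[3] = {(int)(rem % P.n[0]), (int)(rem / P.n[0]), k3};
      int lo[3] = {c[0], c[1], c[2]};
      int hi[3] = {c[0], c[1], c[2]};
      hi[a] += 1;
      if (P.mode == 1 && hi[a] >= P.n[a]) hi[a] = 0;
      int alo = G.actid[lin(G.m, lo[0], lo[1], lo[2])];
      int ahi = G.actid[lin(G.m, hi[0], hi[1], hi[2])];
      double v = 0;
      if (alo >= 0) v += 0.5 * u[a][alo];
      if (ahi >= 0) v += 0.5 * u[a][ahi];
      acc += v;
    }
    mean_v[a] = acc / (double)N;
  }

  out["mean_v"] = mean_v;
  out["converged"] = converged;
  out["iterations"] = iters;
  out["rel_residual"] = relres;
  out["div_inf"] = div_inf;
  out["mom_rel"] = mom_rel;
  out["residual_history"] = NumericVector(hist.begin(), hist.end());
  out["n_unknowns"] = P.g[0].nun + P.g[1].nun + P.g[2].nun;
  if (want_fields) {
    List vf(3);
    for (int c = 0; c < 3; ++c) {
      NumericVector arr((R_xlen_t)P.g[c].m[0] * P.g[c].m[1] * P.g[c].m[2]);
      for (int i = 0; i < P.g[c].nun; ++i) arr[P.g[c].face[i]] = u[c][i];
      arr.attr("dim") = IntegerVector::create(P.g[c].m[0], P.g[c].m[1],
                                              P.g[c].m[2]);
      vf[c] = arr;
    }
    out["velocity"] = vf;
    NumericVector parr(N);
    for (int ip = 0; ip < P.np; ++ip) parr[P.pcell[ip]] = p[ip];
    parr.attr("dim") = dim;
    out["pressure"] = parr;
  }
  return out;
}

// Debug/verification helper: apply the discrete operator to given fields.
// Returns momentum residual A u - D^T p - f and divergence D u.
// [[Rcpp::export]]
List cpp_stokes_apply(IntegerVector fluid, IntegerVector dim, int k, int mode,
                      List velocity, NumericVector pressure) {
  Problem P;
  P.n[0] = dim[0]; P.n[1] = dim[1]; P.n[2] = dim[2];
  P.k = k; P.mode = mode;
  P.fluid = INTEGER(fluid);
  R_xlen_t N = (R_xlen_t)P.n[0] * P.n[1] * P.n[2];
  for (int c = 0; c < 3; ++c) build_comp(P, c);
  P.pid.assign(N, -1);
  for (R_xlen_t i = 0; i < N; ++i)
    if (P.fluid[i]) { P.pid[i] = P.np++; P.pcell.push_back(i); }
  std::vector<double> u[3], gp[3];
  for (int c = 0; c < 3; ++c) {
    NumericVector arr = velocity[c];
    u[c].assign(P.g[c].nun, 0.0);
    gp[c].assign(P.g[c].nun, 0.0);
    for (int i = 0; i < P.g[c].nun; ++i) u[c][i] = arr[P.g[c].face[i]];
  }
  std::vector<double> p(P.np);
  for (int ip = 0; ip < P.np; ++ip) p[ip] = pressure[P.pcell[ip]];
  divT(P, p, gp);
  List mom(3);
  for (int c = 0; c < 3; ++c) {
    std::vector<double> Au(P.g[c].nun);
    amul(P.g[c], u[c], Au);
    NumericVector res((R_xlen_t)P.g[c].m[0] * P.g[c].m[1] * P.g[c].m[2]);
    for (int i = 0; i < P.g[c].nun; ++i) {
      double f = (c == k) ? P.g[c].wgt[i] : 0.0;
      res[P.g[c].face[i]] = Au[i] - gp[c][i] - f;
    }
    res.attr("dim") = IntegerVector::create(P.g[c].m[0], P.g[c].m[1],
                                            P.g[c].m[2]);
    mom[c] = res;
  }
  std::vector<double> dv(P.np);
  divergence(P, u, dv);
  NumericVector dout(N);
  for (int ip = 0; ip < P.np; ++ip) dout[P.pcell[ip]] = dv[ip];
  dout.attr("dim") = dim;
  return List::create(_["momentum"] = mom, _["div"] = dout);
}
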