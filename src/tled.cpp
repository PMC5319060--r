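#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Total-Lagrangian explicit dynamics on uniform hexahedral meshes.
// All spatial shape derivatives are taken in the rest configuration and
// precomputed on the R side (identical for every element of a uniform grid):
// dhdX is (8*nq) x 3, quadrature weights qw already carry the element volume.
// Interface (split) vertices are massless slaves: their two side positions
// are reconstructed from master nodes by fixed MLS weights, and any element
// force landing on a slave is redistributed to that side's support nodes.

// hourglass base vectors for VTK hexahedron node ordering
static const double HG[4][8] = {
  { 1, -1,  1, -1,  1, -1,  1, -1},   // xi*eta
  { 1,  1, -1, -1, -1, -1,  1,  1},   // eta*zeta
  { 1, -1, -1,  1, -1,  1,  1, -1},   // xi*zeta
  {-1,  1, -1,  1,  1, -1,  1, -1}    // xi*eta*zeta
};

static inline void stop_inverted(int e) {
  Rcpp::stop("element inversion (element %d): det F <= 0", e + 1);
}

// first Piola-Kirchhoff stress P = F * S of the compressible Neo-Hookean
// material, S = mu (I - C^-1) + lambda ln(J) C^-1. Throws on J <= 0.
static inline void neo_hookean_P(const double F[3][3], double mu, double lam,
                                 double Pout[3][3], int elem_id) {
  double J =
    F[0][0]*(F[1][1]*F[2][2] - F[1][2]*F[2][1]) -
    F[0][1]*(F[1][0]*F[2][2] - F[1][2]*F[2][0]) +
    F[0][2]*(F[1][0]*F[2][1] - F[1][1]*F[2][0]);
  if (!(J > 0.0)) stop_inverted(elem_id);
  double C[3][3], Ci[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = i; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += F[k][i]*F[k][j];
      C[i][j] = C[j][i] = s;
    }
  double dC =
    C[0][0]*(C[1][1]*C[2][2] - C[1][2]*C[2][1]) -
    C[0][1]*(C[1][0]*C[2][2] - C[1][2]*C[2][0]) +
    C[0][2]*(C[1][0]*C[2][1] - C[1][1]*C[2][0]);
  Ci[0][0] =  (C[1][1]*C[2][2] - C[1][2]*C[2][1]) / dC;
  Ci[0][1] = -(C[0][1]*C[2][2] - C[0][2]*C[2][1]) / dC;
  Ci[0][2] =  (C[0][1]*C[1][2] - C[0][2]*C[1][1]) / dC;
  Ci[1][0] = Ci[0][1];
  Ci[1][1] =  (C[0][0]*C[2][2] - C[0][2]*C[2][0]) / dC;
  Ci[1][2] = -(C[0][0]*C[1][2] - C[0][2]*C[1][0]) / dC;
  Ci[2][0] = Ci[0][2];
  Ci[2][1] = Ci[1][2];
  Ci[2][2] =  (C[0][0]*C[1][1] - C[0][1]*C[1][0]) / dC;
  double lnJ = std::log(J);
  double S[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double I = (i == j) ? 1.0 : 0.0;
      S[i][j] = mu*(I - Ci[i][j]) + lam*lnJ*Ci[i][j];
    }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      Pout[i][j] = F[i][0]*S[0][j] + F[i][1]*S[1][j] + F[i][2]*S[2][j];
    }
}

// element internal-force kernel shared by all entry points; ue is 8 x 3
// (node-major), fel accumulated 8 x 3
static inline void element_forces(const double ue[8][3], double mu, double lam,
                                  const double* dh, int nq, const double* qw,
                                  double hg_kappa, int elem_id,
                                  double fel[8][3]) {
  for (int a = 0; a < 8; ++a)
    for (int i = 0; i < 3; ++i) fel[a][i] = 0.0;
  for (int q = 0; q < nq; ++q) {
    const double* dhq = dh + q*24;        // 8 x 3 block, row-major packed
    double F[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int a = 0; a < 8; ++a) {
      const double* d = dhq + a*3;
      for (int i = 0; i < 3; ++i) {
        F[i][0] += ue[a][i]*d[0];
        F[i][1] += ue[a][i]*d[1];
        F[i][2] += ue[a][i]*d[2];
      }
    }
    double P[3][3];
    neo_hookean_P(F, mu, lam, P, elem_id);
    for (int a = 0; a < 8; ++a) {
      const double* d = dhq + a*3;
      for (int i = 0; i < 3; ++i)
        fel[a][i] += qw[q]*(P[i][0]*d[0] + P[i][1]*d[1] + P[i][2]*d[2]);
    }
  }
  if (hg_kappa > 0.0) {
    for (int m = 0; m < 4; ++m) {
      const double* g = HG[m];
      for (int i = 0; i < 3; ++i) {
        double qm = 0.0;
        for (int a = 0; a < 8; ++a) qm += g[a]*ue[a][i];
        double c = hg_kappa*qm/8.0;
        for (int a = 0; a < 8; ++a) fel[a][i] += c*g[a];
      }
    }
  }
}

// repack column-major (8*nq) x 3 R matrix into row-major blocks
static std::vector<double> pack_dh(const NumericMatrix& dhdX) {
  int rows = dhdX.nrow();
  std::vector<double> dh(rows*3);
  for (int r = 0; r < rows; ++r)
    for (int j = 0; j < 3; ++j) dh[r*3 + j] = dhdX(r, j);
  return dh;
}

// [[Rcpp::export]]
NumericMatrix tled_internal_forces_cpp(IntegerMatrix elems,
                                       NumericVector mu_e, NumericVector lam_e,
                                       NumericMatrix dhdX, NumericVector qw,
                                       NumericVector hg_kappa,
                                       NumericMatrix u, int n_nodes) {
  int E = elems.nrow(), nq = qw.size();
  std::vector<double> dh = pack_dh(dhdX);
  NumericMatrix f(n_nodes, 3);
  double* pf = REAL(f);
  const double* pu = REAL(u);
  const int* pe = INTEGER(elems);
  double ue[8][3], fel[8][3];
  for (int e = 0; e < E; ++e) {
    int nd[8];
    for (int a = 0; a < 8; ++a) {
      nd[a] = pe[a*E + e];
      for (int i = 0; i < 3; ++i) ue[a][i] = pu[i*n_nodes + nd[a]];
    }
    element_forces(ue, mu_e[e], lam_e[e], dh.data(), nq, REAL(qw),
                   hg_kappa[e], e, fel);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) pf[i*n_nodes + nd[a]] += fel[a][i];
  }
  return f;
}

// [[Rcpp::export]]
double tled_strain_energy_cpp(IntegerMatrix elems,
                              NumericVector mu_e, NumericVector lam_e,
                              NumericMatrix dhdX, NumericVector qw,
                              NumericVector hg_kappa, NumericMatrix u) {
  int E = elems.nrow(), nq = qw.size();
  int n = u.nrow();
  std::vector<double> dh = pack_dh(dhdX);
  const double* pu = REAL(u);
  const int* pe = INTEGER(elems);
  double W = 0.0;
  double ue[8][3];
  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < 8; ++a) {
      int nd = pe[a*E + e];
      for (int i = 0; i < 3; ++i) ue[a][i] = pu[i*n + nd];
    }
    for (int q = 0; q < nq; ++q) {
      const double* dhq = dh.data() + q*24;
      double F[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
      for (int a = 0; a < 8; ++a) {
        const double* d = dhq + a*3;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) F[i][j] += ue[a][i]*d[j];
      }
      double J =
        F[0][0]*(F[1][1]*F[2][2] - F[1][2]*F[2][1]) -
        F[0][1]*(F[1][0]*F[2][2] - F[1][2]*F[2][0]) +
        F[0][2]*(F[1][0]*F[2][1] - F[1][1]*F[2][0]);
      if (!(J > 0.0)) stop_inverted(e);
      double I1 = 0.0;
      for (int i = 0; i < 3; ++i)
        for (int k = 0; k < 3; ++k) I1 += F[k][i]*F[k][i];
      double lnJ = std::log(J);
      W += qw[q]*(0.5*mu_e[e]*(I1 - 3.0) - mu_e[e]*lnJ + 0.5*lam_e[e]*lnJ*lnJ);
    }
    if (hg_kappa[e] > 0.0) {
      for (int m = 0; m < 4; ++m)
        for (int i = 0; i < 3; ++i) {
          double qm = 0.0;
          for (int a = 0; a < 8; ++a) qm += HG[m][a]*ue[a][i];
          W += hg_kappa[e]*qm*qm/16.0;
        }
    }
  }
  return W;
}

// Full explicit loop. Central-difference (semi-implicit) update with lumped
// mass and mass-proportional damping D = alpha*M. Prescribed displacements
// ramp linearly over ramp_steps and are then held. Convergence: the max
// free-node velocity component stays below tol for consec_required
// consecutive steps (checked only after the ramp completes).
// [[Rcpp::export]]
List tled_run_cpp(IntegerMatrix elems,
                  NumericVector mu_e, NumericVector lam_e,
                  NumericMatrix dhdX, NumericVector qw,
                  NumericVector hg_kappa,
                  NumericVector mass, IntegerVector free_mask,
                  IntegerVector presc_idx, NumericMatrix presc_disp,
                  int ramp_steps,
                  IntegerVector slave_node,
                  IntegerVector supP_ptr, IntegerVector supP_idx, NumericVector supP_w,
                  IntegerVector supQ_ptr, IntegerVector supQ_idx, NumericVector supQ_w,
                  NumericVector kc,
                  IntegerMatrix elem_slave, IntegerVector elem_side,
                  NumericMatrix u0, NumericMatrix v0, NumericMatrix f_ext,
                  double dt, double alpha, int max_steps, double tol,
                  int consec_required, int min_steps, bool check_convergence) {
  const int E = elems.nrow(), n = mass.size(), S = slave_node.size(),
    nq = qw.size(), P = presc_idx.size();
  std::vector<double> dh = pack_dh(dhdX);
  NumericMatrix u(clone(u0)), v(clone(v0));
  NumericMatrix ubp(S, 3), ubq(S, 3);
  std::vector<double> f(3*n);
  double* pu = REAL(u);
  double* pv = REAL(v);
  double* pbp = REAL(ubp);
  double* pbq = REAL(ubq);
  const double* pfe = REAL(f_ext);
  const double* pm = REAL(mass);
  const double* pqw = REAL(qw);
  const int* pe = INTEGER(elems);
  const int* pes = INTEGER(elem_slave);
  const int* pfree = INTEGER(free_mask);
  const int* pPptr = INTEGER(supP_ptr);
  const int* pQptr = INTEGER(supQ_ptr);
  const int* pPidx = supP_idx.size() ? INTEGER(supP_idx) : nullptr;
  const int* pQidx = supQ_idx.size() ? INTEGER(supQ_idx) : nullptr;
  const double* pPw = supP_w.size() ? REAL(supP_w) : nullptr;
  const double* pQw = supQ_w.size() ? REAL(supQ_w) : nullptr;

  std::vector<int> free_list;
  for (int a = 0; a < n; ++a) if (pfree[a]) free_list.push_back(a);

  int consec = 0, step = 0;
  bool converged = false;
  double maxv = R_PosInf;
  const double damp_a = 1.0 - 0.5*alpha*dt, damp_b = 1.0 + 0.5*alpha*dt;
  double ue[8][3], fel[8][3];

  for (step = 0; step < max_steps; ++step) {
    double r = ramp_steps > 0 ? std::min(1.0, (step + 1.0)/ramp_steps) : 1.0;
    bool ramping = ramp_steps > 0 && (step + 1) < ramp_steps;
    for (int p = 0; p < P; ++p) {
      int idx = presc_idx[p];
      for (int i = 0; i < 3; ++i) {
        pu[i*n + idx] = r*presc_disp(p, i);
        pv[i*n + idx] = ramping ? presc_disp(p, i)/(ramp_steps*dt) : 0.0;
      }
    }
    // slave side positions from masters (fixed MLS weights)
    for (int s = 0; s < S; ++s) {
      double bp[3] = {0, 0, 0}, bq[3] = {0, 0, 0};
      for (int k = pPptr[s]; k < pPptr[s + 1]; ++k) {
        int j = pPidx[k]; double w = pPw[k];
        bp[0] += w*pu[j]; bp[1] += w*pu[n + j]; bp[2] += w*pu[2*n + j];
      }
      for (int k = pQptr[s]; k < pQptr[s + 1]; ++k) {
        int j = pQidx[k]; double w = pQw[k];
        bq[0] += w*pu[j]; bq[1] += w*pu[n + j]; bq[2] += w*pu[2*n + j];
      }
      for (int i = 0; i < 3; ++i) { pbp[i*S + s] = bp[i]; pbq[i*S + s] = bq[i]; }
    }
    // net nodal force: external + coupling - internal
    std::memcpy(f.data(), pfe, sizeof(double)*3*n);
    // penalty coupling: pair force fp = -kc*(ubp - ubq) acts on the
    // parenchyma side; the lesion side receives -fp (action-reaction)
    for (int s = 0; s < S; ++s) {
      double fp[3];
      for (int i = 0; i < 3; ++i) fp[i] = -kc[s]*(pbp[i*S + s] - pbq[i*S + s]);
      for (int k = pPptr[s]; k < pPptr[s + 1]; ++k) {
        int j = pPidx[k]; double w = pPw[k];
        f[j] += w*fp[0]; f[n + j] += w*fp[1]; f[2*n + j] += w*fp[2];
      }
      for (int k = pQptr[s]; k < pQptr[s + 1]; ++k) {
        int j = pQidx[k]; double w = pQw[k];
        f[j] -= w*fp[0]; f[n + j] -= w*fp[1]; f[2*n + j] -= w*fp[2];
      }
    }
    // internal forces; slave corners gathered per element side and
    // redistributed to that side's support nodes
    for (int e = 0; e < E; ++e) {
      int nd[8], sl[8];
      bool any_slave = false;
      for (int a = 0; a < 8; ++a) {
        nd[a] = pe[a*E + e];
        sl[a] = S ? pes[a*E + e] : -1;
        if (sl[a] >= 0) {
          any_slave = true;
          const double* side = elem_side[e] == 0 ? pbp : pbq;
          for (int i = 0; i < 3; ++i) ue[a][i] = side[i*S + sl[a]];
        } else {
          for (int i = 0; i < 3; ++i) ue[a][i] = pu[i*n + nd[a]];
        }
      }
      element_forces(ue, mu_e[e], lam_e[e], dh.data(), nq, pqw,
                     hg_kappa[e], e, fel);
      if (!any_slave) {
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i) f[i*n + nd[a]] -= fel[a][i];
      } else {
        for (int a = 0; a < 8; ++a) {
          if (sl[a] < 0) {
            for (int i = 0; i < 3; ++i) f[i*n + nd[a]] -= fel[a][i];
          } else if (elem_side[e] == 0) {
            for (int k = pPptr[sl[a]]; k < pPptr[sl[a] + 1]; ++k) {
              int j = pPidx[k]; double w = pPw[k];
              for (int i = 0; i < 3; ++i) f[i*n + j] -= w*fel[a][i];
            }
          } else {
            for (int k = pQptr[sl[a]]; k < pQptr[sl[a] + 1]; ++k) {
              int j = pQidx[k]; double w = pQw[k];
              for (int i = 0; i < 3; ++i) f[i*n + j] -= w*fel[a][i];
            }
          }
        }
      }
    }
    // update free masters
    maxv = 0.0;
    for (int a : free_list) {
      double inv_m = 1.0/pm[a];
      for (int i = 0; i < 3; ++i) {
        double vn = (damp_a*pv[i*n + a] + dt*f[i*n + a]*inv_m)/damp_b;
        pv[i*n + a] = vn;
        pu[i*n + a] += dt*vn;
        double av = std::fabs(vn);
        if (av > maxv) maxv = av;
      }
    }
    if (!std::isfinite(maxv))
      stop("divergence: non-finite state at step %d; reduce dt or increase damping", step + 1);
    if (check_convergence && (step + 1) >= ramp_steps && (step + 1) >= min_steps) {
      if (maxv < tol) {
        if (++consec >= consec_required) { converged = true; ++step; break; }
      } else consec = 0;
    }
  }
  // representative slave displacement for whole-mesh exports: parenchyma side
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < 3; ++i) pu[i*n + slave_node[s]] = pbp[i*S + s];
  return List::create(_["u"] = u, _["v"] = v, _["ubp"] = ubp, _["ubq"] = ubq,
                      _["steps"] = step, _["converged"] = converged,
                      _["max_velocity"] = maxv);
}
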