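// Element assembly for the mixed displacement/pressure (P2/P1) biphasic
// equilibrium problem with multiplicative isotropic growth.
//
// Total-Lagrangian weak form on the reference (pre-swelling) configuration:
//   momentum:  int [ P_s - p J F^{-T} ] : grad0(du) dV0 = 0
//   pressure:  int [ k J grad0(q)^T C^{-1} grad0(p) - J Q(p) q
//                    (+ J div_x(v_s) q in quasistatic mode) ] dV0 = 0
// with P_s = lam^3 mu J^{-2/3} (F - (I1/3) F^{-T}) + K (Je - 1) J F^{-T},
// Je = J / lam^3, Q(p) = a - b p. The factor lam^3 is det(Fg): energy per
// unit reference volume of the grown material. The Jacobian below is the
// exact linearization of this residual (checked against finite differences
// in the test suite).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double det3(const double* F) {
  return F[0] * (F[4] * F[8] - F[5] * F[7])
       - F[3] * (F[1] * F[8] - F[2] * F[7])
       + F[6] * (F[1] * F[5] - F[2] * F[4]);
}

// column-major 3x3 inverse
static inline void inv3(const double* F, double J, double* Fi) {
  double iJ = 1.0 / J;
  Fi[0] = (F[4] * F[8] - F[5] * F[7]) * iJ;
  Fi[1] = (F[2] * F[7] - F[1] * F[8]) * iJ;
  Fi[2] = (F[1] * F[5] - F[2] * F[4]) * iJ;
  Fi[3] = (F[5] * F[6] - F[3] * F[8]) * iJ;
  Fi[4] = (F[0] * F[8] - F[2] * F[6]) * iJ;
  Fi[5] = (F[2] * F[3] - F[0] * F[5]) * iJ;
  Fi[6] = (F[3] * F[7] - F[4] * F[6]) * iJ;
  Fi[7] = (F[1] * F[6] - F[0] * F[7]) * iJ;
  Fi[8] = (F[0] * F[4] - F[1] * F[3]) * iJ;
}

// [[Rcpp::export(name = ".cpp_assemble")]]
List cpp_assemble(NumericMatrix nodes,      // np2 x 3 (m), vertices first
                  IntegerMatrix cells10,    // m x 10, 1-based
                  NumericVector wq,         // nq quadrature weights (ref tet)
                  NumericMatrix dNu,        // (10*nq) x 3 ref gradients of P2
                  NumericMatrix Np,         // nq x 4 P1 values
                  NumericVector u,          // 3*np2 displacements (m)
                  NumericVector p,          // nv pressures (Pa)
                  NumericVector lambda_el,  // m growth stretch per element
                  double mu, double K, double khyd,
                  double a_star, double b_star,
                  int jac_mode,             // 0 none, 1 full coupled, 2 uu+pp blocks
                  IntegerVector dofmap,     // ndof -> reduced index (0-based) or -1
                  int n_free, int n_free_u, // free u dofs come first in the reduced order
                  bool quasistatic, double dt, NumericVector u_old) {
  const int m = cells10.nrow();
  const int nq = wq.size();
  const int np2 = nodes.nrow();
  const int ndof = 3 * np2 + p.size();
  NumericVector R(ndof);
  const bool want_jac = jac_mode > 0;
  const bool want_coupling = jac_mode == 1;

  std::vector<int> ti, tj, tiu, tju, tip, tjp;
  std::vector<double> tx, txu, txp;
  if (jac_mode == 1) {
    size_t guess = (size_t)m * 800;
    ti.reserve(guess); tj.reserve(guess); tx.reserve(guess);
  } else if (jac_mode == 2) {
    tiu.reserve((size_t)m * 600); tju.reserve((size_t)m * 600);
    txu.reserve((size_t)m * 600);
    tip.reserve((size_t)m * 16); tjp.reserve((size_t)m * 16);
    txp.reserve((size_t)m * 16);
  }

  double gph[30];           // physical gradients of the 10 P2 fns at one qp
  double Ru[30], Rp[4], Kuu[900], Kup[120], Kpu[120], Kpp[16];
  int gdof[34];

  for (int e = 0; e < m; ++e) {
    // affine map from the reference tetrahedron
    int v0 = cells10(e, 0) - 1, v1 = cells10(e, 1) - 1,
        v2 = cells10(e, 2) - 1, v3 = cells10(e, 3) - 1;
    double Jm[9];
    for (int c = 0; c < 3; ++c) {
      Jm[0 + c] = nodes(v1, c) - nodes(v0, c);
      Jm[3 + c] = nodes(v2, c) - nodes(v0, c);
      Jm[6 + c] = nodes(v3, c) - nodes(v0, c);
    }
    double detJ = det3(Jm);
    if (detJ <= 0) stop("inverted element during assembly (cell %d)", e + 1);
    double Ji[9];
    inv3(Jm, detJ, Ji);

    const double lam = lambda_el[e];
    const double lg3 = lam * lam * lam;

    int nid[10];
    for (int i = 0; i < 10; ++i) nid[i] = cells10(e, i) - 1;
    for (int i = 0; i < 10; ++i)
      for (int c = 0; c < 3; ++c) gdof[3 * i + c] = 3 * nid[i] + c;
    for (int mloc = 0; mloc < 4; ++mloc) gdof[30 + mloc] = 3 * np2 + nid[mloc];

    std::fill(Ru, Ru + 30, 0.0);
    std::fill(Rp, Rp + 4, 0.0);
    if (want_jac) {
      std::fill(Kuu, Kuu + 900, 0.0);
      std::fill(Kup, Kup + 120, 0.0);
      std::fill(Kpu, Kpu + 120, 0.0);
      std::fill(Kpp, Kpp + 16, 0.0);
    }

    for (int q = 0; q < nq; ++q) {
      // physical gradients: g_i = Ji^T * dN_i  (Ji maps ref->phys gradients)
      for (int i = 0; i < 10; ++i) {
        double d0 = dNu(10 * q + i, 0), d1 = dNu(10 * q + i, 1),
               d2 = dNu(10 * q + i, 2);
        gph[3 * i + 0] = Ji[0] * d0 + Ji[1] * d1 + Ji[2] * d2;
        gph[3 * i + 1] = Ji[3] * d0 + Ji[4] * d1 + Ji[5] * d2;
        gph[3 * i + 2] = Ji[6] * d0 + Ji[7] * d1 + Ji[8] * d2;
      }
      // F = I + grad0 u, stored column-major: F[r + 3c] = F_{r,c}
      double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
      double gv[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0}; // grad0 v (quasistatic)
      for (int i = 0; i < 10; ++i) {
        double u0 = u[3 * nid[i]], u1 = u[3 * nid[i] + 1], u2 = u[3 * nid[i] + 2];
        double g0 = gph[3 * i], g1 = gph[3 * i + 1], g2 = gph[3 * i + 2];
        F[0] += u0 * g0; F[3] += u0 * g1; F[6] += u0 * g2;
        F[1] += u1 * g0; F[4] += u1 * g1; F[7] += u1 * g2;
        F[2] += u2 * g0; F[5] += u2 * g1; F[8] += u2 * g2;
        if (quasistatic) {
          double w0 = (u0 - u_old[3 * nid[i]]) / dt;
          double w1 = (u1 - u_old[3 * nid[i] + 1]) / dt;
          double w2 = (u2 - u_old[3 * nid[i] + 2]) / dt;
          gv[0] += w0 * g0; gv[3] += w0 * g1; gv[6] += w0 * g2;
          gv[1] += w1 * g0; gv[4] += w1 * g1; gv[7] += w1 * g2;
          gv[2] += w2 * g0; gv[5] += w2 * g1; gv[8] += w2 * g2;
        }
      }
      double Jdet = det3(F);
      if (Jdet <= 0) stop("inverted element during assembly (cell %d)", e + 1);
      double Fi[9];
      inv3(F, Jdet, Fi); // Fi[r + 3c] = (F^{-1})_{r,c}
      double Je = Jdet / lg3;
      double I1 = 0;
      for (int k = 0; k < 9; ++k) I1 += F[k] * F[k];
      double c1 = lg3 * mu * std::pow(Jdet, -2.0 / 3.0);

      // pressure and gradients at qp
      double pq = 0, gp[3] = {0, 0, 0};
      double Gp[12]; // physical gradients of P1 fns (4 x 3)
      {
        // P1 ref gradients: L1 = 1-x-y-z -> (-1,-1,-1); L2..L4 unit vectors
        static const double dl[12] = {-1, -1, -1, 1, 0, 0, 0, 1, 0, 0, 0, 1};
        for (int mm = 0; mm < 4; ++mm) {
          double d0 = dl[3 * mm], d1 = dl[3 * mm + 1], d2 = dl[3 * mm + 2];
          Gp[3 * mm + 0] = Ji[0] * d0 + Ji[1] * d1 + Ji[2] * d2;
          Gp[3 * mm + 1] = Ji[3] * d0 + Ji[4] * d1 + Ji[5] * d2;
          Gp[3 * mm + 2] = Ji[6] * d0 + Ji[7] * d1 + Ji[8] * d2;
          double pv = p[nid[mm]];
          pq += pv * Np(q, mm);
          gp[0] += pv * Gp[3 * mm + 0];
          gp[1] += pv * Gp[3 * mm + 1];
          gp[2] += pv * Gp[3 * mm + 2];
        }
      }

      // per-node helper vectors: f_i = F g_i, h_i = F^{-T} g_i
      // ((F^{-T})_{r,k} = (F^{-1})_{k,r} = Fi[k + 3r])
      double hv[30], fv[30];
      for (int i = 0; i < 10; ++i) {
        double g0 = gph[3 * i], g1 = gph[3 * i + 1], g2 = gph[3 * i + 2];
        fv[3 * i + 0] = F[0] * g0 + F[3] * g1 + F[6] * g2;
        fv[3 * i + 1] = F[1] * g0 + F[4] * g1 + F[7] * g2;
        fv[3 * i + 2] = F[2] * g0 + F[5] * g1 + F[8] * g2;
        hv[3 * i + 0] = Fi[0] * g0 + Fi[1] * g1 + Fi[2] * g2;
        hv[3 * i + 1] = Fi[3] * g0 + Fi[4] * g1 + Fi[5] * g2;
        hv[3 * i + 2] = Fi[6] * g0 + Fi[7] * g1 + Fi[8] * g2;
      }

      double wd = wq[q] * detJ;
      double cvol = K * (Je - 1) * Jdet - pq * Jdet; // volumetric + fluid coeff

      // momentum residual
      for (int i = 0; i < 10; ++i)
        for (int c = 0; c < 3; ++c)
          Ru[3 * i + c] += wd * (c1 * (fv[3 * i + c] - I1 / 3.0 * hv[3 * i + c])
                                 + cvol * hv[3 * i + c]);

      // C^{-1} gp = F^{-1} (F^{-T} gp)
      double hp[3], cgp[3];
      hp[0] = Fi[0] * gp[0] + Fi[1] * gp[1] + Fi[2] * gp[2];
      hp[1] = Fi[3] * gp[0] + Fi[4] * gp[1] + Fi[5] * gp[2];
      hp[2] = Fi[6] * gp[0] + Fi[7] * gp[1] + Fi[8] * gp[2]; // = F^{-T} gp = grad_x p
      cgp[0] = Fi[0] * hp[0] + Fi[3] * hp[1] + Fi[6] * hp[2];
      cgp[1] = Fi[1] * hp[0] + Fi[4] * hp[1] + Fi[7] * hp[2];
      cgp[2] = Fi[2] * hp[0] + Fi[5] * hp[1] + Fi[8] * hp[2];

      double Qsrc = a_star - b_star * pq;
      double trv = 0;
      if (quasistatic) {
        // tr(grad_x v) = F^{-T} : grad0 v
        trv = 0;
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c)
            trv += Fi[c + 3 * r] * gv[r + 3 * c];
      }

      for (int mm = 0; mm < 4; ++mm) {
        double diff = Gp[3 * mm] * cgp[0] + Gp[3 * mm + 1] * cgp[1]
                    + Gp[3 * mm + 2] * cgp[2];
        Rp[mm] += wd * (khyd * Jdet * diff - Jdet * Qsrc * Np(q, mm)
                        + (quasistatic ? Jdet * trv * Np(q, mm) : 0.0));
      }

      if (!want_jac) continue;

      // ---- Kuu ----
      // Rank-structured form of the exact tangent:
      //   Kuu[(i,c),(j,d)] = wd * ( c1 * dcd * (g_i.g_j)
      //                             + s1 * h_ic h_jd
      //                             + s2 * (h_ic f_jd + f_ic h_jd)
      //                             + s3 * h_jc h_id )
      double KJ = K * Jdet;
      double s1 = (2.0 / 9.0) * I1 * c1 + KJ * (2 * Je - 1) - pq * Jdet;
      double s2 = -(2.0 / 3.0) * c1;
      double s3 = (I1 / 3.0) * c1 - KJ * (Je - 1) + pq * Jdet;
      for (int j = 0; j < 10; ++j) {
        double gj0 = gph[3 * j], gj1 = gph[3 * j + 1], gj2 = gph[3 * j + 2];
        for (int i = 0; i < 10; ++i) {
          double gg = wd * c1 * (gph[3 * i] * gj0 + gph[3 * i + 1] * gj1
                                 + gph[3 * i + 2] * gj2);
          Kuu[(3 * i + 0) + 30 * (3 * j + 0)] += gg;
          Kuu[(3 * i + 1) + 30 * (3 * j + 1)] += gg;
          Kuu[(3 * i + 2) + 30 * (3 * j + 2)] += gg;
        }
      }
      for (int jd = 0; jd < 30; ++jd) {
        double a1 = wd * (s1 * hv[jd] + s2 * fv[jd]);
        double a2 = wd * s2 * hv[jd];
        double* col = Kuu + 30 * jd;
        for (int ic = 0; ic < 30; ++ic)
          col[ic] += a1 * hv[ic] + a2 * fv[ic];
      }
      for (int d = 0; d < 3; ++d)
        for (int c = 0; c < 3; ++c) {
          double w3 = wd * s3;
          for (int j = 0; j < 10; ++j) {
            double hjc = w3 * hv[3 * j + c];
            double* col = Kuu + 30 * (3 * j + d);
            for (int i = 0; i < 10; ++i)
              col[3 * i + c] += hjc * hv[3 * i + d];
          }
        }
      if (want_coupling) {
      // ---- Kup ----
      for (int mm = 0; mm < 4; ++mm) {
        double npm = Np(q, mm);
        for (int i = 0; i < 10; ++i)
          for (int c = 0; c < 3; ++c)
            Kup[(3 * i + c) + 30 * mm] += -wd * Jdet * hv[3 * i + c] * npm;
      }
      // ---- Kpu ----
      for (int j = 0; j < 10; ++j) {
        // cj = C^{-1} g_j = F^{-1} h_j
        double h0 = hv[3 * j], h1 = hv[3 * j + 1], h2 = hv[3 * j + 2];
        double cj[3];
        cj[0] = Fi[0] * h0 + Fi[3] * h1 + Fi[6] * h2;
        cj[1] = Fi[1] * h0 + Fi[4] * h1 + Fi[7] * h2;
        cj[2] = Fi[2] * h0 + Fi[5] * h1 + Fi[8] * h2;
        double cj_gp = cj[0] * gp[0] + cj[1] * gp[1] + cj[2] * gp[2];
        for (int d = 0; d < 3; ++d) {
          double hjd = hv[3 * j + d];
          // m_d = column d of F^{-1}
          double md[3] = {Fi[0 + 3 * d], Fi[1 + 3 * d], Fi[2 + 3 * d]};
          double gxp_d = hp[d]; // (grad_x p)_d
          double contr = 0;    // (h_j m_d^T) : grad0 v (quasistatic geometry term)
          if (quasistatic)
            for (int c = 0; c < 3; ++c)
              contr += (h0 * gv[0 + 3 * c] + h1 * gv[1 + 3 * c]
                        + h2 * gv[2 + 3 * c]) * md[c];
          for (int mm = 0; mm < 4; ++mm) {
            double Gm_cgp = Gp[3 * mm] * cgp[0] + Gp[3 * mm + 1] * cgp[1]
                          + Gp[3 * mm + 2] * cgp[2];
            double Gm_cj = Gp[3 * mm] * cj[0] + Gp[3 * mm + 1] * cj[1]
                         + Gp[3 * mm + 2] * cj[2];
            double Gm_md = Gp[3 * mm] * md[0] + Gp[3 * mm + 1] * md[1]
                         + Gp[3 * mm + 2] * md[2];
            double val = khyd * Jdet * (hjd * Gm_cgp - Gm_cj * gxp_d
                                        - Gm_md * cj_gp)
                       - Qsrc * Jdet * hjd * Np(q, mm);
            if (quasistatic)
              val += Jdet * Np(q, mm) * (hjd * trv - contr + hjd / dt);
            Kpu[mm + 4 * (3 * j + d)] += wd * val;
          }
        }
      }
      } // want_coupling
      // ---- Kpp ----
      for (int mm = 0; mm < 4; ++mm) {
        // C^{-1} Gp_mm
        double g0 = Gp[3 * mm], g1 = Gp[3 * mm + 1], g2 = Gp[3 * mm + 2];
        double t0 = Fi[0] * g0 + Fi[1] * g1 + Fi[2] * g2;
        double t1 = Fi[3] * g0 + Fi[4] * g1 + Fi[5] * g2;
        double t2 = Fi[6] * g0 + Fi[7] * g1 + Fi[8] * g2;
        double cg0 = Fi[0] * t0 + Fi[3] * t1 + Fi[6] * t2;
        double cg1 = Fi[1] * t0 + Fi[4] * t1 + Fi[7] * t2;
        double cg2 = Fi[2] * t0 + Fi[5] * t1 + Fi[8] * t2;
        for (int rr = 0; rr < 4; ++rr) {
          double diff = Gp[3 * rr] * cg0 + Gp[3 * rr + 1] * cg1
                      + Gp[3 * rr + 2] * cg2;
          Kpp[rr + 4 * mm] += wd * (khyd * Jdet * diff
                                    + Jdet * b_star * Np(q, mm) * Np(q, rr));
        }
      }
    } // qp loop

    // scatter element residual
    for (int i = 0; i < 30; ++i) R[gdof[i]] += Ru[i];
    for (int mm = 0; mm < 4; ++mm) R[gdof[30 + mm]] += Rp[mm];

    if (jac_mode == 1) {
      int red[34];
      for (int i = 0; i < 34; ++i) red[i] = dofmap[gdof[i]];
      for (int j = 0; j < 30; ++j) {
        if (red[j] < 0) continue;
        for (int i = 0; i < 30; ++i) {
          if (red[i] < 0) continue;
          double v = Kuu[i + 30 * j];
          if (v != 0) { ti.push_back(red[i] + 1); tj.push_back(red[j] + 1); tx.push_back(v); }
        }
        for (int mm = 0; mm < 4; ++mm) {
          if (red[30 + mm] < 0) continue;
          double v = Kpu[mm + 4 * j];
          if (v != 0) { ti.push_back(red[30 + mm] + 1); tj.push_back(red[j] + 1); tx.push_back(v); }
        }
      }
      for (int mm = 0; mm < 4; ++mm) {
        if (red[30 + mm] < 0) continue;
        for (int i = 0; i < 30; ++i) {
          if (red[i] < 0) continue;
          double v = Kup[i + 30 * mm];
          if (v != 0) { ti.push_back(red[i] + 1); tj.push_back(red[30 + mm] + 1); tx.push_back(v); }
        }
        for (int rr = 0; rr < 4; ++rr) {
          if (red[30 + rr] < 0) continue;
          double v = Kpp[rr + 4 * mm];
          if (v != 0) { ti.push_back(red[30 + rr] + 1); tj.push_back(red[30 + mm] + 1); tx.push_back(v); }
        }
      }
    } else if (jac_mode == 2) {
      // diagonal blocks only, each indexed within its own free-dof set
      int red[34];
      for (int i = 0; i < 34; ++i) red[i] = dofmap[gdof[i]];
      for (int j = 0; j < 30; ++j) {
        if (red[j] < 0) continue;
        for (int i = 0; i < 30; ++i) {
          if (red[i] < 0) continue;
          double v = Kuu[i + 30 * j];
          if (v != 0) { tiu.push_back(red[i] + 1); tju.push_back(red[j] + 1); txu.push_back(v); }
        }
      }
      for (int mm = 0; mm < 4; ++mm) {
        if (red[30 + mm] < 0) continue;
        for (int rr = 0; rr < 4; ++rr) {
          if (red[30 + rr] < 0) continue;
          double v = Kpp[rr + 4 * mm];
          if (v != 0) {
            tip.push_back(red[30 + rr] - n_free_u + 1);
            tjp.push_back(red[30 + mm] - n_free_u + 1);
            txp.push_back(v);
          }
        }
      }
    }
  } // element loop

  List out = List::create(_["R"] = R);
  if (jac_mode == 1) {
    out["i"] = IntegerVector(ti.begin(), ti.end());
    out["j"] = IntegerVector(tj.begin(), tj.end());
    out["x"] = NumericVector(tx.begin(), tx.end());
    out["n_free"] = n_free;
  } else if (jac_mode == 2) {
    out["iu"] = IntegerVector(tiu.begin(), tiu.end());
    out["ju"] = IntegerVector(tju.begin(), tju.end());
    out["xu"] = NumericVector(txu.begin(), txu.end());
    out["ip"] = IntegerVector(tip.begin(), tip.end());
    out["jp"] = IntegerVector(tjp.begin(), tjp.end());
    out["xp"] = NumericVector(txp.begin(), txp.end());
  }
  return out;
}

// deformation gradients and pressure values at quadrature points, for
// post-processing (stress evaluation, volume integrals)
// [[Rcpp::export(name = ".cpp_qp_fields")]]
List cpp_qp_fields(NumericMatrix nodes, IntegerMatrix cells10,
                   NumericVector wq, NumericMatrix dNu, NumericMatrix Np,
                   NumericVector u, NumericVector p) {
  const int m = cells10.nrow();
  const int nq = wq.size();
  NumericMatrix Fout(m * nq, 9);
  NumericVector pout(m * nq), wdet(m * nq);
  double gph[30];
  for (int e = 0; e < m; ++e) {
    int v0 = cells10(e, 0) - 1, v1 = cells10(e, 1) - 1,
        v2 = cells10(e, 2) - 1, v3 = cells10(e, 3) - 1;
    double Jm[9];
    for (int c = 0; c < 3; ++c) {
      Jm[0 + c] = nodes(v1, c) - nodes(v0, c);
      Jm[3 + c] = nodes(v2, c) - nodes(v0, c);
      Jm[6 + c] = nodes(v3, c) - nodes(v0, c);
    }
    double detJ = det3(Jm);
    double Ji[9];
    inv3(Jm, detJ, Ji);
    int nid[10];
    for (int i = 0; i < 10; ++i) nid[i] = cells10(e, i) - 1;
    for (int q = 0; q < nq; ++q) {
      for (int i = 0; i < 10; ++i) {
        double d0 = dNu(10 * q + i, 0), d1 = dNu(10 * q + i, 1),
               d2 = dNu(10 * q + i, 2);
        gph[3 * i + 0] = Ji[0] * d0 + Ji[1] * d1 + Ji[2] * d2;
        gph[3 * i + 1] = Ji[3] * d0 + Ji[4] * d1 + Ji[5] * d2;
        gph[3 * i + 2] = Ji[6] * d0 + Ji[7] * d1 + Ji[8] * d2;
      }
      double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
      for (int i = 0; i < 10; ++i) {
        double u0 = u[3 * nid[i]], u1 = u[3 * nid[i] + 1], u2 = u[3 * nid[i] + 2];
        double g0 = gph[3 * i], g1 = gph[3 * i + 1], g2 = gph[3 * i + 2];
        F[0] += u0 * g0; F[3] += u0 * g1; F[6] += u0 * g2;
        F[1] += u1 * g0; F[4] += u1 * g1; F[7] += u1 * g2;
        F[2] += u2 * g0; F[5] += u2 * g1; F[8] += u2 * g2;
      }
      double pq = 0;
      for (int mm = 0; mm < 4; ++mm) pq += p[nid[mm]] * Np(q, mm);
      int row = e * nq + q;
      for (int k = 0; k < 9; ++k) Fout(row, k) = F[k];
      pout[row] = pq;
      wdet[row] = wq[q] * detJ;
    }
  }
  return List::create(_["F"] = Fout, _["p"] = pout, _["wdet"] = wdet);
}
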