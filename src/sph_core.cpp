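// Corrected-kernel total-Lagrangian SPH core for the aortic wall model.
//
// Geometry is a 2D annular sector (unit reference depth, fixed axial
// stretch); rotational periodicity is handled per directed edge via a
// rotation code s in {-1, 0, +1}: the neighbour j participates through its
// image rotated by s * sector angle.  All per-edge quantities (reference
// offsets, kernel weights, corrected gradients) are precomputed after every
// change of the neighbour lists and reused by the relaxation loop.
//
// Units: lengths in micrometres, stresses in kPa, volumes in um^3 (area x
// unit depth); particle masses are fictitious (dynamic relaxation only).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// ---- Spiky kernel ---------------------------------------------------------

inline double spiky_w(double R, double h) {
  if (R >= h) return 0.0;
  double d = h - R;
  return 10.0 * d * d * d / (PI_ * h * h * h * h * h);
}

// radial derivative d(xi)/dR  (<= 0)
inline double spiky_dw(double R, double h) {
  if (R >= h) return 0.0;
  double d = h - R;
  return -30.0 * d * d / (PI_ * h * h * h * h * h);
}

// [[Rcpp::export]]
NumericVector cpp_kernel_weight(NumericVector R, double h) {
  int n = R.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = spiky_w(R[i], h);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_kernel_gradient(NumericMatrix offset, double h) {
  int n = offset.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double rx = offset(i, 0), ry = offset(i, 1);
    double R = std::sqrt(rx * rx + ry * ry);
    if (R <= 0.0 || R >= h) { out(i, 0) = 0.0; out(i, 1) = 0.0; continue; }
    double s = spiky_dw(R, h) / R;
    out(i, 0) = s * rx;
    out(i, 1) = s * ry;
  }
  return out;
}

// ---- neighbour search -----------------------------------------------------

// Brute-force neighbour search with rotational-periodic images.  Returns a
// CSR structure of directed edges (i -> j, rotation code s).
// [[Rcpp::export]]
List cpp_build_edges(NumericMatrix X, double h, double sector, bool periodic) {
  int n = X.nrow();
  std::vector< std::vector<int> > nbr(n), rotc(n);
  double cs = std::cos(sector), sn = std::sin(sector);
  double h2 = h * h;
  for (int i = 0; i < n; ++i) {
    double xi = X(i, 0), yi = X(i, 1);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double xj = X(j, 0), yj = X(j, 1);
      // s = 0 (true position)
      double dx = xj - xi, dy = yj - yi;
      if (dx * dx + dy * dy < h2) { nbr[i].push_back(j); rotc[i].push_back(0); }
      if (periodic) {
        // s = +1 : rotate j by +sector
        double xp = cs * xj - sn * yj, yp = sn * xj + cs * yj;
        dx = xp - xi; dy = yp - yi;
        if (dx * dx + dy * dy < h2) { nbr[i].push_back(j); rotc[i].push_back(1); }
        // s = -1
        double xm = cs * xj + sn * yj, ym = -sn * xj + cs * yj;
        dx = xm - xi; dy = ym - yi;
        if (dx * dx + dy * dy < h2) { nbr[i].push_back(j); rotc[i].push_back(-1); }
      }
    }
  }
  int m = 0;
  for (int i = 0; i < n; ++i) m += (int) nbr[i].size();
  IntegerVector ptr(n + 1), idx(m), rot(m);
  int k = 0;
  ptr[0] = 0;
  for (int i = 0; i < n; ++i) {
    for (size_t q = 0; q < nbr[i].size(); ++q) {
      idx[k] = nbr[i][q];
      rot[k] = rotc[i][q];
      ++k;
    }
    ptr[i + 1] = k;
  }
  return List::create(_["ptr"] = ptr, _["idx"] = idx, _["rot"] = rot);
}

// rotation matrix for code s
inline void rotmat(int s, double sector, double &c, double &sn) {
  if (s == 0) { c = 1.0; sn = 0.0; }
  else { c = std::cos(s * sector); sn = std::sin(s * sector); }
}

// ---- correction matrices and corrected gradients --------------------------

// Recomputes, over alive edges only:
//   Rj   (m x 2)  reference offset to the (possibly imaged) neighbour
//   w    (m)      kernel weight
//   cgrad(m x 2)  A_i^{-1} grad_X xi(R_j)           (used for F_i and P_i term)
//   cback(m x 2)  Q_s A_j^{-1} Q_s^T grad_X xi(-R_j) (neighbour's corrected
//                 gradient toward i, expressed in i's frame)
//   A, Ainv (n x 4, row-major 2x2), cond (n)
// [[Rcpp::export]]
List cpp_correct(NumericMatrix X, NumericVector V,
                 IntegerVector ptr, IntegerVector idx, IntegerVector rot,
                 LogicalVector alive, double h, double sector) {
  int n = X.nrow(), m = idx.size();
  NumericMatrix Rj(m, 2), cgrad(m, 2), cback(m, 2);
  NumericVector w(m);
  NumericMatrix A(n, 4), Ainv(n, 4);
  NumericVector cond(n);

  // pass 1: offsets, weights, raw gradients, A_i
  std::vector<double> gx(m), gy(m);
  for (int i = 0; i < n; ++i) {
    double a11 = 0, a12 = 0, a21 = 0, a22 = 0;
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      int j = idx[e];
      double c, sn;
      rotmat(rot[e], sector, c, sn);
      double xj = c * X(j, 0) - sn * X(j, 1);
      double yj = sn * X(j, 0) + c * X(j, 1);
      double rx = xj - X(i, 0), ry = yj - X(i, 1);
      Rj(e, 0) = rx; Rj(e, 1) = ry;
      double R = std::sqrt(rx * rx + ry * ry);
      w[e] = spiky_w(R, h);
      double s = (R > 0.0) ? spiky_dw(R, h) / R : 0.0;
      gx[e] = s * rx; gy[e] = s * ry;
      if (!alive[e]) continue;
      double Vj = V[j];
      a11 += Vj * gx[e] * rx; a12 += Vj * gx[e] * ry;
      a21 += Vj * gy[e] * rx; a22 += Vj * gy[e] * ry;
    }
    A(i, 0) = a11; A(i, 1) = a12; A(i, 2) = a21; A(i, 3) = a22;
    double det = a11 * a22 - a12 * a21;
    // condition number from singular values of 2x2
    double t1 = a11 * a11 + a12 * a12 + a21 * a21 + a22 * a22;
    double t2 = std::sqrt(std::max(0.0, t1 * t1 - 4.0 * det * det));
    double smax = std::sqrt(std::max(0.0, (t1 + t2) / 2.0));
    double smin = std::sqrt(std::max(0.0, (t1 - t2) / 2.0));
    cond[i] = (smin > 0.0) ? smax / smin : R_PosInf;
    if (det == 0.0) { Ainv(i, 0) = NA_REAL; continue; }
    Ainv(i, 0) =  a22 / det; Ainv(i, 1) = -a12 / det;
    Ainv(i, 2) = -a21 / det; Ainv(i, 3) =  a11 / det;
  }

  // pass 2: corrected gradients (need all Ainv)
  for (int i = 0; i < n; ++i) {
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      int j = idx[e];
      cgrad(e, 0) = Ainv(i, 0) * gx[e] + Ainv(i, 1) * gy[e];
      cgrad(e, 1) = Ainv(i, 2) * gx[e] + Ainv(i, 3) * gy[e];
      // neighbour's corrected gradient toward i, rotated into i's frame:
      // Q_s A_j^{-1} Q_s^T applied to grad evaluated at -R_j (= -gx,-gy)
      double c, sn;
      rotmat(rot[e], sector, c, sn);
      // M = Q A Q^T with A = Ainv_j
      double b11 = Ainv(j, 0), b12 = Ainv(j, 1), b21 = Ainv(j, 2), b22 = Ainv(j, 3);
      double q11 = c * b11 - sn * b21, q12 = c * b12 - sn * b22;
      double q21 = sn * b11 + c * b21, q22 = sn * b12 + c * b22;
      double m11 = q11 * c - q12 * sn, m12 = q11 * sn + q12 * c;
      double m21 = q21 * c - q22 * sn, m22 = q21 * sn + q22 * c;
      cback(e, 0) = m11 * (-gx[e]) + m12 * (-gy[e]);
      cback(e, 1) = m21 * (-gx[e]) + m22 * (-gy[e]);
    }
  }

  return List::create(_["Rj"] = Rj, _["w"] = w,
                      _["cgrad"] = cgrad, _["cback"] = cback,
                      _["A"] = A, _["Ainv"] = Ainv, _["cond"] = cond);
}

// ---- deformation gradient -------------------------------------------------

// [[Rcpp::export]]
List cpp_deformation(NumericMatrix x, NumericVector V,
                     IntegerVector ptr, IntegerVector idx, IntegerVector rot,
                     LogicalVector alive, NumericMatrix cgrad,
                     double sector, double lambda_z) {
  int n = x.nrow();
  NumericMatrix F(n, 4);
  NumericVector J(n);
  for (int i = 0; i < n; ++i) {
    double f11 = 0, f12 = 0, f21 = 0, f22 = 0;
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      if (!alive[e]) continue;
      int j = idx[e];
      double c, sn;
      rotmat(rot[e], sector, c, sn);
      double xj = c * x(j, 0) - sn * x(j, 1);
      double yj = sn * x(j, 0) + c * x(j, 1);
      double rx = xj - x(i, 0), ry = yj - x(i, 1);
      double Vg0 = V[j] * cgrad(e, 0), Vg1 = V[j] * cgrad(e, 1);
      f11 += rx * Vg0; f12 += rx * Vg1;
      f21 += ry * Vg0; f22 += ry * Vg1;
    }
    F(i, 0) = f11; F(i, 1) = f12; F(i, 2) = f21; F(i, 3) = f22;
    J[i] = (f11 * f22 - f12 * f21) * lambda_z;
  }
  return List::create(_["F"] = F, _["J"] = J);
}

// ---- constitutive evaluation ----------------------------------------------

// Material parameter matrix columns (one row per particle):
//  0 group (0 disrupted/free, 1 M_el, 2 M_int, 3 A, 4 GAG)
//  1 phi_e  2 mu  3 lambda_hat  4 Ge_r  5 Ge_t  6 Ge_z
//  7..34  fibre families k = 1..4, 7 columns each:
//         [w (= phi^ck * beta), G, sin2a, c1p, c2p, c1m, c2m]
//  35 act_on  36 act_phi (phi^c2)  37 Tmax  38 lmax  39 lmin
//  40 mu_gag  41 pi_swell (kPa)  42 theta_ref (rad)
static const int MP_NCOL = 43;

struct StressOut {
  double P11, P12, P21, P22;     // first Piola-Kirchhoff (in-plane)
  double W;                      // strain energy density
  double szz;                    // out-of-plane Cauchy (report only)
  bool ok;
};

inline StressOut particle_stress(const double *mp,
                                 double f11, double f12, double f21, double f22,
                                 double xcur, double ycur,
                                 double lambda_z, double act_scale,
                                 double sw_scale = 1.0) {
  StressOut out;
  out.ok = true;
  out.W = 0.0; out.szz = 0.0;
  out.P11 = out.P12 = out.P21 = out.P22 = 0.0;
  int group = (int) mp[0];
  if (group == 0) return out;

  double J2 = f11 * f22 - f12 * f21;
  double J = J2 * lambda_z;
  if (!(J > 0.0)) { out.ok = false; return out; }

  // C = F^T F (in-plane block)
  double C11 = f11 * f11 + f21 * f21;
  double C12 = f11 * f12 + f21 * f22;
  double C22 = f12 * f12 + f22 * f22;

  // F^{-T} (in-plane)
  double Fi11 =  f22 / J2, Fi12 = -f21 / J2;   // F^{-T} = (1/det) [f22 -f21; -f12 f11]
  double Fi21 = -f12 / J2, Fi22 =  f11 / J2;

  if (group == 4) {
    // GAG pool: modified neo-Hookean + optional Gibbs-Donnan swelling
    double mug = mp[40], pisw = mp[41] * sw_scale;
    // B = F F^T
    double B11 = f11 * f11 + f12 * f12;
    double B12 = f11 * f21 + f12 * f22;
    double B22 = f21 * f21 + f22 * f22;
    // sigma = (mu/J)(B - I) - pi I ; P = J sigma F^{-T}
    double s11 = (mug / J) * (B11 - 1.0) - pisw;
    double s12 = (mug / J) * B12;
    double s22 = (mug / J) * (B22 - 1.0) - pisw;
    out.P11 = J * (s11 * Fi11 + s12 * Fi21);
    out.P12 = J * (s11 * Fi12 + s12 * Fi22);
    out.P21 = J * (s12 * Fi11 + s22 * Fi21);
    out.P22 = J * (s12 * Fi12 + s22 * Fi22);
    out.szz = (mug / J) * (lambda_z * lambda_z - 1.0) - pisw;
    // energy of the neo-Hookean part (swelling is not stored elastically)
    double I1 = B11 + B22 + lambda_z * lambda_z;
    out.W = 0.5 * mug * (I1 - 3.0); // small-strain bookkeeping only
    return out;
  }

  double phie = mp[1], mu = mp[2], lh = mp[3];
  double Ger = mp[4], Get = mp[5], Gez = mp[6];
  double th = mp[42];
  double cth = std::cos(th), sth = std::sin(th);
  // reference radial and circumferential unit vectors
  double erx = cth, ery = sth, etx = -sth, ety = cth;

  double Ctt = etx * (C11 * etx + C12 * ety) + ety * (C12 * etx + C22 * ety);
  double Crr = erx * (C11 * erx + C12 * ery) + ery * (C12 * erx + C22 * ery);

  double lnJ = std::log(J);

  // C^{-1} (in-plane)
  double detC = C11 * C22 - C12 * C12;
  double Ci11 = C22 / detC, Ci12 = -C12 / detC, Ci22 = C11 / detC;

  // elastin (modified neo-Hookean with diagonal deposition prestretch)
  double g2r = Ger * Ger, g2t = Get * Get, g2z = Gez * Gez;
  double I1e = g2r * Crr + g2t * Ctt + g2z * lambda_z * lambda_z;
  double vol = -mu + lh * lnJ;
  // S_e = mu (g2r er x er + g2t et x et) + vol * C^{-1}
  double S11 = phie * (mu * (g2r * erx * erx + g2t * etx * etx) + vol * Ci11);
  double S12 = phie * (mu * (g2r * erx * ery + g2t * etx * ety) + vol * Ci12);
  double S22 = phie * (mu * (g2r * ery * ery + g2t * ety * ety) + vol * Ci22);
  out.W = phie * (0.5 * mu * (I1e - 3.0) - mu * lnJ + 0.5 * lh * lnJ * lnJ);
  out.szz = phie * (mu * g2z * lambda_z * lambda_z + vol);

  // fibre families (theta-z plane; only the circumferential projection acts
  // in-plane, the axial projection contributes to szz)
  double fibw = 0.0;
  for (int k = 0; k < 4; ++k) {
    const double *fp = mp + 7 + 7 * k;
    double wk = fp[0];
    if (wk <= 0.0) continue;
    double G = fp[1], s2 = fp[2];
    double G2 = G * G;
    double I4 = G2 * (s2 * Ctt + (1.0 - s2) * lambda_z * lambda_z);
    double c1 = (I4 >= 1.0) ? fp[3] : fp[5];
    double c2 = (I4 >= 1.0) ? fp[4] : fp[6];
    double d = I4 - 1.0;
    double ex = std::exp(c2 * d * d);
    out.W += wk * (c1 / (4.0 * c2)) * (ex - 1.0);
    double dWdI4_2 = wk * c1 * d * ex;       // 2 * dW/dI4
    fibw += dWdI4_2 * G2 * s2;
    out.szz += dWdI4_2 * G2 * (1.0 - s2) * lambda_z * lambda_z;
  }
  S11 += fibw * etx * etx;
  S12 += fibw * etx * ety;
  S22 += fibw * ety * ety;
  out.szz /= J;

  // P = F S
  out.P11 = f11 * S11 + f12 * S12;
  out.P12 = f11 * S12 + f12 * S22;
  out.P21 = f21 * S11 + f22 * S12;
  out.P22 = f21 * S12 + f22 * S22;

  // active smooth-muscle tone (current circumferential direction)
  if (mp[35] > 0.5 && act_scale > 0.0) {
    double lt = std::sqrt(Ctt);
    double lmax = mp[38], lmin = mp[39];
    if (lt > lmin && lt <= lmax) {
      double q = (lmax - lt) / (lmax - lmin);
      double sact = act_scale * mp[36] * mp[37] * lt * (1.0 - q * q);
      double phc = std::atan2(ycur, xcur);
      double ecx = -std::sin(phc), ecy = std::cos(phc);
      // P_act = J sact (ec x ec) F^{-T}
      double a11 = ecx * ecx, a12 = ecx * ecy, a22 = ecy * ecy;
      out.P11 += J * sact * (a11 * Fi11 + a12 * Fi21);
      out.P12 += J * sact * (a11 * Fi12 + a12 * Fi22);
      out.P21 += J * sact * (a12 * Fi11 + a22 * Fi21);
      out.P22 += J * sact * (a12 * Fi12 + a22 * Fi22);
    }
  }
  return out;
}

// Exposed single-shot stress evaluation (used by R-level tests/analysis).
// [[Rcpp::export]]
List cpp_stress(NumericMatrix F, NumericMatrix mp, NumericMatrix x,
                double lambda_z, double act_scale) {
  int n = F.nrow();
  NumericMatrix P(n, 4), sig(n, 4);
  NumericVector W(n), szz(n), J(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    double f11 = F(i, 0), f12 = F(i, 1), f21 = F(i, 2), f22 = F(i, 3);
    // NumericMatrix is column-major; copy the row out
    double row[MP_NCOL];
    for (int c = 0; c < MP_NCOL; ++c) row[c] = mp(i, c);
    StressOut s = particle_stress(row, f11, f12, f21, f22, x(i, 0), x(i, 1),
                                  lambda_z, act_scale);
    ok[i] = s.ok;
    P(i, 0) = s.P11; P(i, 1) = s.P12; P(i, 2) = s.P21; P(i, 3) = s.P22;
    W[i] = s.W; szz[i] = s.szz;
    double J2 = f11 * f22 - f12 * f21;
    J[i] = J2 * lambda_z;
    if (s.ok && J[i] > 0) {
      sig(i, 0) = (s.P11 * f11 + s.P12 * f12) / J[i];
      sig(i, 1) = (s.P11 * f21 + s.P12 * f22) / J[i];
      sig(i, 2) = (s.P21 * f11 + s.P22 * f12) / J[i];
      sig(i, 3) = (s.P21 * f21 + s.P22 * f22) / J[i];
    }
  }
  return List::create(_["P"] = P, _["sigma"] = sig, _["W"] = W,
                      _["szz"] = szz, _["J"] = J, _["ok"] = ok);
}

// ---- internal + hourglass forces ------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix P, NumericVector V,
                         IntegerVector ptr, IntegerVector idx, IntegerVector rot,
                         LogicalVector alive,
                         NumericMatrix cgrad, NumericMatrix cback,
                         double sector) {
  int n = P.nrow();
  NumericMatrix f(n, 2);
  for (int i = 0; i < n; ++i) {
    double fx = 0, fy = 0;
    double p11 = P(i, 0), p12 = P(i, 1), p21 = P(i, 2), p22 = P(i, 3);
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      if (!alive[e]) continue;
      int j = idx[e];
      double c, sn;
      rotmat(rot[e], sector, c, sn);
      // neighbour stress rotated to i's frame: Q P_j Q^T
      double b11 = P(j, 0), b12 = P(j, 1), b21 = P(j, 2), b22 = P(j, 3);
      double q11 = c * b11 - sn * b21, q12 = c * b12 - sn * b22;
      double q21 = sn * b11 + c * b21, q22 = sn * b12 + c * b22;
      double pj11 = q11 * c - q12 * sn, pj12 = q11 * sn + q12 * c;
      double pj21 = q21 * c - q22 * sn, pj22 = q21 * sn + q22 * c;
      double ViVj = V[i] * V[j];
      fx += ViVj * (p11 * cgrad(e, 0) + p12 * cgrad(e, 1)
                    - (pj11 * cback(e, 0) + pj12 * cback(e, 1)));
      fy += ViVj * (p21 * cgrad(e, 0) + p22 * cgrad(e, 1)
                    - (pj21 * cback(e, 0) + pj22 * cback(e, 1)));
    }
    f(i, 0) = fx; f(i, 1) = fy;
  }
  return f;
}

// [[Rcpp::export]]
NumericMatrix cpp_hourglass(NumericMatrix F, NumericMatrix x, NumericVector V,
                            IntegerVector ptr, IntegerVector idx, IntegerVector rot,
                            LogicalVector alive,
                            NumericMatrix Rj, NumericVector w,
                            double sector, double alpha, double E) {
  int n = F.nrow();
  NumericMatrix f(n, 2);
  if (alpha <= 0.0 || E <= 0.0) return f;
  for (int i = 0; i < n; ++i) {
    double fx = 0, fy = 0;
    double fi11 = F(i, 0), fi12 = F(i, 1), fi21 = F(i, 2), fi22 = F(i, 3);
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      if (!alive[e]) continue;
      int j = idx[e];
      double c, sn;
      rotmat(rot[e], sector, c, sn);
      double xj = c * x(j, 0) - sn * x(j, 1);
      double yj = sn * x(j, 0) + c * x(j, 1);
      double rx = xj - x(i, 0), ry = yj - x(i, 1);
      double r = std::sqrt(rx * rx + ry * ry);
      if (r <= 0.0) continue;
      double Rx = Rj(e, 0), Ry = Rj(e, 1);
      double R2 = Rx * Rx + Ry * Ry;
      // affine prediction errors projected on the current pair direction
      double di = ((fi11 * Rx + fi12 * Ry) - rx) * rx / r
                + ((fi21 * Rx + fi22 * Ry) - ry) * ry / r;
      // neighbour F rotated: Q F_j Q^T
      double b11 = F(j, 0), b12 = F(j, 1), b21 = F(j, 2), b22 = F(j, 3);
      double q11 = c * b11 - sn * b21, q12 = c * b12 - sn * b22;
      double q21 = sn * b11 + c * b21, q22 = sn * b12 + c * b22;
      double fj11 = q11 * c - q12 * sn, fj12 = q11 * sn + q12 * c;
      double fj21 = q21 * c - q22 * sn, fj22 = q21 * sn + q22 * c;
      double dj = ((fj11 * Rx + fj12 * Ry) - rx) * rx / r
                + ((fj21 * Rx + fj22 * Ry) - ry) * ry / r;
      double coef = -alpha * E * V[i] * V[j] * w[e] * (di + dj) / (2.0 * R2 * r);
      fx += coef * rx;
      fy += coef * ry;
    }
    f(i, 0) = fx; f(i, 1) = fy;
  }
  return f;
}

// ---- relaxation loop ------------------------------------------------------

// Damped leapfrog dynamics until quasi-static equilibrium.  Returns the
// final state, converged stresses, and diagnostics.
//
// control list fields:
//   dt, max_steps, check_every, tol_ke, tol_f, damp, eta, alpha, E_hg,
//   lambda_z, ramp_steps, act0, act1, r_rim0, r_rim1
// rim: 0-based indices of inner-rim particles (radial position prescribed)
// frozen: per-particle flag; frozen particles do not move
// [[Rcpp::export]]
List cpp_relax(NumericMatrix X, NumericMatrix x0, NumericMatrix v0,
               NumericVector V, NumericVector mass, NumericMatrix mp,
               IntegerVector ptr, IntegerVector idx, IntegerVector rot,
               LogicalVector alive,
               NumericMatrix cgrad, NumericMatrix cback,
               NumericMatrix Rj, NumericVector w,
               IntegerVector rim, LogicalVector frozen,
               double sector, List control) {
  int n = X.nrow();
  double dt        = as<double>(control["dt"]);
  int max_steps    = as<int>(control["max_steps"]);
  int check_every  = as<int>(control["check_every"]);
  double tol_ke    = as<double>(control["tol_ke"]);
  double tol_f     = as<double>(control["tol_f"]);
  double damp      = as<double>(control["damp"]);
  double eta       = as<double>(control["eta"]);
  double alpha     = as<double>(control["alpha"]);
  double E_hg      = as<double>(control["E_hg"]);
  double lambda_z  = as<double>(control["lambda_z"]);
  int ramp_steps   = as<int>(control["ramp_steps"]);
  double act0      = as<double>(control["act0"]);
  double act1      = as<double>(control["act1"]);
  double rim0      = as<double>(control["r_rim0"]);
  double rim1      = as<double>(control["r_rim1"]);
  double sw0       = control.containsElementNamed("sw0") ?
                       as<double>(control["sw0"]) : 1.0;
  double sw1       = control.containsElementNamed("sw1") ?
                       as<double>(control["sw1"]) : 1.0;
  bool kin_damp    = control.containsElementNamed("kin_damp") ?
                       as<bool>(control["kin_damp"]) : true;
  // per-step displacement cap (fraction of spacing): rides out transient
  // stiffening without inverting elements; inactive near equilibrium
  double vcap      = control.containsElementNamed("vcap") ?
                       as<double>(control["vcap"]) : R_PosInf;

  // Copy everything the stepper touches into contiguous plain arrays:
  // SEXP accessor indirection in the inner loops costs an order of
  // magnitude at these problem sizes.
  std::vector<double> x(2 * n), v(2 * n), Vv(n), mv(n);
  for (int i = 0; i < n; ++i) {
    x[2 * i] = x0(i, 0); x[2 * i + 1] = x0(i, 1);
    v[2 * i] = v0(i, 0); v[2 * i + 1] = v0(i, 1);
    Vv[i] = V[i]; mv[i] = mass[i];
  }
  int m_edges = idx.size();
  std::vector<int> eptr(n + 1), ejdx;
  std::vector<double> ece, ese, eViVj, ecg0, ecg1, ecb0, ecb1, eRx, eRy, eR2, ew;
  ejdx.reserve(m_edges); ece.reserve(m_edges); ese.reserve(m_edges);
  {
    int k = 0;
    for (int i = 0; i < n; ++i) {
      eptr[i] = k;
      for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
        if (!alive[e]) continue;
        double c, sn;
        rotmat(rot[e], sector, c, sn);
        ejdx.push_back(idx[e]);
        ece.push_back(c); ese.push_back(sn);
        eViVj.push_back(V[i] * V[idx[e]]);
        ecg0.push_back(cgrad(e, 0)); ecg1.push_back(cgrad(e, 1));
        ecb0.push_back(cback(e, 0)); ecb1.push_back(cback(e, 1));
        eRx.push_back(Rj(e, 0)); eRy.push_back(Rj(e, 1));
        eR2.push_back(Rj(e, 0) * Rj(e, 0) + Rj(e, 1) * Rj(e, 1));
        ew.push_back(w[e]);
        ++k;
      }
    }
    eptr[n] = k;
  }
  std::vector<double> F(4 * n, 0.0), Fprev(4 * n, 0.0), P(4 * n, 0.0);
  std::vector<double> fint(2 * n, 0.0);
  NumericVector Wout(n), szz(n), Jout(n);

  // copy material rows once (column-major access is slow in the loop)
  std::vector<double> M(n * MP_NCOL);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < MP_NCOL; ++c) M[i * MP_NCOL + c] = mp(i, c);
  std::vector<char> isfrozen(n, 0);
  for (int i = 0; i < n; ++i) isfrozen[i] = frozen[i] ? 1 : 0;

  int nrim = rim.size();
  std::vector<char> isrim_flag(n, 0);
  for (int q = 0; q < nrim; ++q) isrim_flag[rim[q]] = 1;
  std::string status = "max_steps";
  double KEpeak = 0.0, KEprev = R_PosInf, KE = 0.0;
  double maxf = R_PosInf, fscale = 1.0;
  int step = 0;
  std::vector<double> ke_log;
  bool have_Fprev = false;

  for (step = 0; step < max_steps; ++step) {
    double s01 = (ramp_steps > 0) ? std::min(1.0, (double)(step + 1) / ramp_steps) : 1.0;
    double smooth = s01 * s01 * (3.0 - 2.0 * s01);
    double act_scale = act0 + (act1 - act0) * smooth;
    double sw_scale = sw0 + (sw1 - sw0) * smooth;
    double rim_r = rim0 + (rim1 - rim0) * smooth;

    // deformation gradients
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      double f11 = 0, f12 = 0, f21 = 0, f22 = 0;
      double xi0 = x[2 * i], xi1 = x[2 * i + 1];
      for (int e = eptr[i]; e < eptr[i + 1]; ++e) {
        int j = ejdx[e];
        double c = ece[e], sn = ese[e];
        double rx = c * x[2 * j] - sn * x[2 * j + 1] - xi0;
        double ry = sn * x[2 * j] + c * x[2 * j + 1] - xi1;
        double Vg0 = Vv[j] * ecg0[e], Vg1 = Vv[j] * ecg1[e];
        f11 += rx * Vg0; f12 += rx * Vg1;
        f21 += ry * Vg0; f22 += ry * Vg1;
      }
      if ((int) M[i * MP_NCOL] == 0) { f11 = 1; f12 = 0; f21 = 0; f22 = 1; }
      F[4 * i] = f11; F[4 * i + 1] = f12; F[4 * i + 2] = f21; F[4 * i + 3] = f22;
      if (f11 * f22 - f12 * f21 <= 0.0 && (int) M[i * MP_NCOL] != 0) bad = true;
    }
    if (bad) { status = "inversion"; break; }
    if (!have_Fprev) { Fprev = F; have_Fprev = true; }

    // stresses (constitutive + viscous)
    for (int i = 0; i < n; ++i) {
      double f11 = F[4 * i], f12 = F[4 * i + 1], f21 = F[4 * i + 2], f22 = F[4 * i + 3];
      StressOut s = particle_stress(&M[i * MP_NCOL], f11, f12, f21, f22,
                                    x[2 * i], x[2 * i + 1], lambda_z,
                                    act_scale, sw_scale);
      if (!s.ok) { bad = true; break; }
      double p11 = s.P11, p12 = s.P12, p21 = s.P21, p22 = s.P22;
      if (eta > 0.0 && (int) M[i * MP_NCOL] != 0) {
        // P_visc = 2 eta J d F^{-T}, d = sym(Fdot F^{-1})
        double J2 = f11 * f22 - f12 * f21;
        double J = J2 * lambda_z;
        double fd11 = (f11 - Fprev[4 * i]) / dt, fd12 = (f12 - Fprev[4 * i + 1]) / dt;
        double fd21 = (f21 - Fprev[4 * i + 2]) / dt, fd22 = (f22 - Fprev[4 * i + 3]) / dt;
        double g11 = f22 / J2, g12 = -f12 / J2, g21 = -f21 / J2, g22 = f11 / J2; // F^{-1}
        double l11 = fd11 * g11 + fd12 * g21, l12 = fd11 * g12 + fd12 * g22;
        double l21 = fd21 * g11 + fd22 * g21, l22 = fd21 * g12 + fd22 * g22;
        double d11 = l11, d22 = l22, d12 = 0.5 * (l12 + l21);
        double Fi11 = g11, Fi12 = g21, Fi21 = g12, Fi22 = g22; // F^{-T}
        double cvisc = 2.0 * eta * J;
        p11 += cvisc * (d11 * Fi11 + d12 * Fi21);
        p12 += cvisc * (d11 * Fi12 + d12 * Fi22);
        p21 += cvisc * (d12 * Fi11 + d22 * Fi21);
        p22 += cvisc * (d12 * Fi12 + d22 * Fi22);
      }
      P[4 * i] = p11; P[4 * i + 1] = p12; P[4 * i + 2] = p21; P[4 * i + 3] = p22;
      Wout[i] = s.W; szz[i] = s.szz;
    }
    if (bad) { status = "inversion"; break; }
    Fprev = F;

    // forces (internal + hourglass)
    bool do_hg = (alpha > 0.0 && E_hg > 0.0);
    for (int i = 0; i < n; ++i) {
      double fx = 0, fy = 0;
      double p11 = P[4 * i], p12 = P[4 * i + 1], p21 = P[4 * i + 2], p22 = P[4 * i + 3];
      double fi11 = F[4 * i], fi12 = F[4 * i + 1], fi21 = F[4 * i + 2], fi22 = F[4 * i + 3];
      double xi0 = x[2 * i], xi1 = x[2 * i + 1];
      for (int e = eptr[i]; e < eptr[i + 1]; ++e) {
        int j = ejdx[e];
        double c = ece[e], sn = ese[e];
        double b11 = P[4 * j], b12 = P[4 * j + 1], b21 = P[4 * j + 2], b22 = P[4 * j + 3];
        double q11 = c * b11 - sn * b21, q12 = c * b12 - sn * b22;
        double q21 = sn * b11 + c * b21, q22 = sn * b12 + c * b22;
        double pj11 = q11 * c - q12 * sn, pj12 = q11 * sn + q12 * c;
        double pj21 = q21 * c - q22 * sn, pj22 = q21 * sn + q22 * c;
        fx += eViVj[e] * (p11 * ecg0[e] + p12 * ecg1[e]
                          - (pj11 * ecb0[e] + pj12 * ecb1[e]));
        fy += eViVj[e] * (p21 * ecg0[e] + p22 * ecg1[e]
                          - (pj21 * ecb0[e] + pj22 * ecb1[e]));

        if (do_hg) {
          double rx = c * x[2 * j] - sn * x[2 * j + 1] - xi0;
          double ry = sn * x[2 * j] + c * x[2 * j + 1] - xi1;
          double r = std::sqrt(rx * rx + ry * ry);
          if (r > 0.0) {
            double Rx = eRx[e], Ry = eRy[e];
            double di = ((fi11 * Rx + fi12 * Ry) - rx) * rx / r
                      + ((fi21 * Rx + fi22 * Ry) - ry) * ry / r;
            double a11 = F[4 * j], a12 = F[4 * j + 1], a21 = F[4 * j + 2], a22 = F[4 * j + 3];
            double u11 = c * a11 - sn * a21, u12 = c * a12 - sn * a22;
            double u21 = sn * a11 + c * a21, u22 = sn * a12 + c * a22;
            double fj11 = u11 * c - u12 * sn, fj12 = u11 * sn + u12 * c;
            double fj21 = u21 * c - u22 * sn, fj22 = u21 * sn + u22 * c;
            double dj = ((fj11 * Rx + fj12 * Ry) - rx) * rx / r
                      + ((fj21 * Rx + fj22 * Ry) - ry) * ry / r;
            double coef = -alpha * E_hg * eViVj[e] * ew[e] * (di + dj)
                          / (2.0 * eR2[e] * r);
            fx += coef * rx;
            fy += coef * ry;
          }
        }
      }
      fint[2 * i] = fx; fint[2 * i + 1] = fy;
    }

    // leapfrog (semi-implicit Euler / kick-drift), damping, constraints
    double near_conv = (KEpeak > 0.0 && KE / KEpeak < 4.0 * tol_ke) ? 1.0 : damp;
    for (int i = 0; i < n; ++i) {
      if (isfrozen[i]) { v[2 * i] = 0; v[2 * i + 1] = 0; continue; }
      double a0 = fint[2 * i] / mv[i], a1 = fint[2 * i + 1] / mv[i];
      double v0_ = (v[2 * i] + dt * a0) * near_conv;
      double v1_ = (v[2 * i + 1] + dt * a1) * near_conv;
      double vm2 = v0_ * v0_ + v1_ * v1_;
      if (vm2 > vcap * vcap) {
        double sc = vcap / std::sqrt(vm2);
        v0_ *= sc; v1_ *= sc;
      }
      v[2 * i] = v0_; v[2 * i + 1] = v1_;
      x[2 * i] += dt * v0_;
      x[2 * i + 1] += dt * v1_;
      if (!R_finite(x[2 * i]) || !R_finite(x[2 * i + 1])) { bad = true; }
    }
    if (bad) { status = "nan"; break; }
    // project rim particles onto the prescribed radius
    for (int q = 0; q < nrim; ++q) {
      int i = rim[q];
      double r = std::sqrt(x[2 * i] * x[2 * i] + x[2 * i + 1] * x[2 * i + 1]);
      if (r > 0) {
        double sc = rim_r / r;
        x[2 * i] *= sc; x[2 * i + 1] *= sc;
        // remove radial velocity
        double ux = x[2 * i] / rim_r, uy = x[2 * i + 1] / rim_r;
        double vr = v[2 * i] * ux + v[2 * i + 1] * uy;
        v[2 * i] -= vr * ux; v[2 * i + 1] -= vr * uy;
      }
    }

    // convergence bookkeeping
    if ((step + 1) % check_every == 0) {
      KE = 0.0; maxf = 0.0;
      double fsc_acc = 0.0, Pmax = 0.0;
      for (int i = 0; i < n; ++i) {
        if (isfrozen[i]) continue;
        KE += 0.5 * mv[i] * (v[2 * i] * v[2 * i] + v[2 * i + 1] * v[2 * i + 1]);
        double p11 = P[4 * i], p12 = P[4 * i + 1], p21 = P[4 * i + 2], p22 = P[4 * i + 3];
        double pm = std::max(std::max(std::fabs(p11), std::fabs(p12)),
                             std::max(std::fabs(p21), std::fabs(p22)));
        if (pm > Pmax) Pmax = pm;
        for (int e = eptr[i]; e < eptr[i + 1]; ++e) {
          double tx = p11 * ecg0[e] + p12 * ecg1[e];
          double ty = p21 * ecg0[e] + p22 * ecg1[e];
          fsc_acc += eViVj[e] * std::sqrt(tx * tx + ty * ty);
        }
        if (isrim_flag[i]) continue;
        double fm = std::sqrt(fint[2 * i] * fint[2 * i] + fint[2 * i + 1] * fint[2 * i + 1]);
        if (fm > maxf) maxf = fm;
      }
      fscale = fsc_acc / (double) n;
      ke_log.push_back(KE);
      if (KE > KEpeak) KEpeak = KE;
      bool ramp_done = (step + 1) >= ramp_steps;
      // a stress-free system (e.g. no prestretch) is trivially equilibrated:
      // the relative criteria are 0/0 there
      bool trivial = (Pmax < 1e-8);
      if (ramp_done &&
          (trivial || (KEpeak > 0 &&
                       KE / KEpeak < tol_ke && maxf < tol_f * fscale))) {
        status = "converged"; ++step; break;
      }
      // kinetic damping: kill velocities when KE passes a peak
      if (kin_damp && ramp_done && KE < KEprev) {
        for (int i = 0; i < 2 * n; ++i) v[i] = 0;
        KEprev = 0.0;
      } else {
        KEprev = KE;
      }
    }
  }

  NumericMatrix Fout(n, 4), Pout(n, 4), sig(n, 4);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 4; ++c) { Fout(i, c) = F[4 * i + c]; Pout(i, c) = P[4 * i + c]; }
    double f11 = F[4 * i], f12 = F[4 * i + 1], f21 = F[4 * i + 2], f22 = F[4 * i + 3];
    double J = (f11 * f22 - f12 * f21) * lambda_z;
    Jout[i] = J;
    if (J > 0) {
      double p11 = P[4 * i], p12 = P[4 * i + 1], p21 = P[4 * i + 2], p22 = P[4 * i + 3];
      sig(i, 0) = (p11 * f11 + p12 * f12) / J;
      sig(i, 1) = (p11 * f21 + p12 * f22) / J;
      sig(i, 2) = (p21 * f11 + p22 * f12) / J;
      sig(i, 3) = (p21 * f21 + p22 * f22) / J;
    }
  }
  NumericMatrix fmat(n, 2), xout(n, 2), vout(n, 2);
  for (int i = 0; i < n; ++i) {
    fmat(i, 0) = fint[2 * i]; fmat(i, 1) = fint[2 * i + 1];
    xout(i, 0) = x[2 * i]; xout(i, 1) = x[2 * i + 1];
    vout(i, 0) = v[2 * i]; vout(i, 1) = v[2 * i + 1];
  }

  return List::create(_["x"] = xout, _["v"] = vout, _["F"] = Fout, _["P"] = Pout,
                      _["sigma"] = sig, _["J"] = Jout, _["W"] = Wout,
                      _["szz"] = szz, _["force"] = fmat,
                      _["steps"] = step, _["status"] = status,
                      _["ke"] = wrap(ke_log), _["ke_peak"] = KEpeak,
                      _["maxf"] = maxf, _["fscale"] = fscale);
}
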