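// Hot loops of the IB-LBM solver: D3Q19 LBGK collide/stream with Guo forcing
// and halfway bounce-back (optionally moving walls), immersed-boundary
// spreading/interpolation with the 2-point hat kernel, and analytic membrane
// forces (Skalak in-plane, dihedral bending, global area/volume constraints).
//
// Conventions shared with the R side:
//  * populations stored direction-fastest: f[i + 19*cell], cell = x + nx*(y + ny*z)
//  * lattice coordinates are 0-based, site centres at integers 0..n-1
//  * faces/edges arrive 0-based from R wrappers
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const int EX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1,-1, 1, 1,-1, 0, 0, 0, 0};
const int EY[19] = {0, 0, 0, 1,-1, 0, 0, 0, 0,-1, 1, 0, 0,-1, 1,-1, 1,-1, 1};
const int EZ[19] = {0, 0, 0, 0, 0, 1,-1, 1,-1, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1};
const int OPP[19] = {0, 2, 1, 4, 3, 6, 5, 8, 7,10, 9,12,11,14,13,16,15,18,17};
const double W0 = 1.0/3.0, W1 = 1.0/18.0, W2 = 1.0/36.0;
const double W[19] = {W0, W1,W1,W1,W1,W1,W1,
                      W2,W2,W2,W2,W2,W2,W2,W2,W2,W2,W2,W2};

inline int wrapi(int i, int n) {
  if (i < 0) return i + n;
  if (i >= n) return i - n;
  return i;
}

inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}
inline double dot3(const double a[3], const double b[3]) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}

} // namespace

// One LBGK step: macroscopic moments (with half-force correction), BGK
// collision with Guo source, propagation with periodic wrap, halfway
// bounce-back into solid sites (Ladd correction when the wall moves).
// rho/ux/uy/uz are filled with the *pre-collision* (time t) fields, which is
// what the immersed boundary interpolates. Writes the streamed populations
// into fnew; caller swaps the two buffers.
// [[Rcpp::export]]
void cpp_lbm_step(NumericVector f, NumericVector fnew,
                  NumericVector rho, NumericVector ux,
                  NumericVector uy, NumericVector uz,
                  IntegerVector solid,
                  NumericVector wux, NumericVector wuy, NumericVector wuz,
                  NumericVector Fx, NumericVector Fy, NumericVector Fz,
                  double tau, int nx, int ny, int nz) {
  const bool hasF = Fx.size() > 0;
  const bool hasW = wux.size() > 0;
  const double pref = 1.0 - 0.5/tau;
  const double invtau = 1.0/tau;

  double *pf = REAL(f), *pn = REAL(fnew);
  double *pr = REAL(rho), *pux = REAL(ux), *puy = REAL(uy), *puz = REAL(uz);
  int *ps = INTEGER(solid);
  double *pFx = hasF ? REAL(Fx) : nullptr;
  double *pFy = hasF ? REAL(Fy) : nullptr;
  double *pFz = hasF ? REAL(Fz) : nullptr;
  double *pwx = hasW ? REAL(wux) : nullptr;
  double *pwy = hasW ? REAL(wuy) : nullptr;
  double *pwz = hasW ? REAL(wuz) : nullptr;

  for (int z = 0; z < nz; ++z)
  for (int y = 0; y < ny; ++y)
  for (int x = 0; x < nx; ++x) {
    const R_xlen_t c = (R_xlen_t)x + (R_xlen_t)nx*(y + (R_xlen_t)ny*z);
    if (ps[c]) {
      pr[c] = 1.0;
      pux[c] = hasW ? pwx[c] : 0.0;
      puy[c] = hasW ? pwy[c] : 0.0;
      puz[c] = hasW ? pwz[c] : 0.0;
      continue;
    }
    const double *fc = pf + 19*c;
    double r = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
    for (int i = 0; i < 19; ++i) {
      const double v = fc[i];
      r += v; mx += EX[i]*v; my += EY[i]*v; mz += EZ[i]*v;
    }
    const double fx = hasF ? pFx[c] : 0.0;
    const double fy = hasF ? pFy[c] : 0.0;
    const double fz = hasF ? pFz[c] : 0.0;
    const double invr = 1.0/r;
    const double vx = (mx + 0.5*fx)*invr;
    const double vy = (my + 0.5*fy)*invr;
    const double vz = (mz + 0.5*fz)*invr;
    pr[c] = r; pux[c] = vx; puy[c] = vy; puz[c] = vz;
    const double usq = vx*vx + vy*vy + vz*vz;

    for (int i = 0; i < 19; ++i) {
      const double eu = EX[i]*vx + EY[i]*vy + EZ[i]*vz;
      const double feq = W[i]*r*(1.0 + 3.0*eu + 4.5*eu*eu - 1.5*usq);
      double src = 0.0;
      if (hasF) {
        const double emuF = (EX[i]-vx)*fx + (EY[i]-vy)*fy + (EZ[i]-vz)*fz;
        const double eF = EX[i]*fx + EY[i]*fy + EZ[i]*fz;
        src = pref*W[i]*(3.0*emuF + 9.0*eu*eF);
      }
      const double fpost = fc[i] - invtau*(fc[i] - feq) + src;

      const int xt = wrapi(x + EX[i], nx);
      const int yt = wrapi(y + EY[i], ny);
      const int zt = wrapi(z + EZ[i], nz);
      const R_xlen_t ct = (R_xlen_t)xt + (R_xlen_t)nx*(yt + (R_xlen_t)ny*zt);
      if (ps[ct]) {
        double corr = 0.0;
        if (hasW) {
          const double euw = EX[i]*pwx[ct] + EY[i]*pwy[ct] + EZ[i]*pwz[ct];
          corr = 6.0*W[i]*r*euw;  // 2 w_i rho (e_i . u_w)/cs^2
        }
        pn[19*c + OPP[i]] = fpost - corr;
      } else {
        pn[19*ct + i] = fpost;
      }
    }
  }
}

// Macroscopic moments only (no collision): rho = sum_i f_i,
// u = (sum_i e_i f_i + F/2)/rho. Used for diagnostics after the last step.
// [[Rcpp::export]]
void cpp_macroscopic(NumericVector f, NumericVector rho,
                     NumericVector ux, NumericVector uy, NumericVector uz,
                     IntegerVector solid,
                     NumericVector wux, NumericVector wuy, NumericVector wuz,
                     NumericVector Fx, NumericVector Fy, NumericVector Fz) {
  const bool hasF = Fx.size() > 0;
  const bool hasW = wux.size() > 0;
  const R_xlen_t ncell = rho.size();
  double *pf = REAL(f);
  for (R_xlen_t c = 0; c < ncell; ++c) {
    if (solid[c]) {
      rho[c] = 1.0;
      ux[c] = hasW ? wux[c] : 0.0;
      uy[c] = hasW ? wuy[c] : 0.0;
      uz[c] = hasW ? wuz[c] : 0.0;
      continue;
    }
    const double *fc = pf + 19*c;
    double r = 0, mx = 0, my = 0, mz = 0;
    for (int i = 0; i < 19; ++i) {
      const double v = fc[i];
      r += v; mx += EX[i]*v; my += EY[i]*v; mz += EZ[i]*v;
    }
    const double fx = hasF ? Fx[c] : 0.0;
    const double fy = hasF ? Fy[c] : 0.0;
    const double fz = hasF ? Fz[c] : 0.0;
    rho[c] = r;
    ux[c] = (mx + 0.5*fx)/r;
    uy[c] = (my + 0.5*fy)/r;
    uz[c] = (mz + 0.5*fz)/r;
  }
}

// Spread Lagrangian node forces to the 2x2x2 neighbourhood of each node with
// the tensor-product hat kernel. Accumulates into Fx/Fy/Fz.
// [[Rcpp::export]]
void cpp_spread(NumericMatrix pos, NumericMatrix frc,
                NumericVector Fx, NumericVector Fy, NumericVector Fz,
                int nx, int ny, int nz,
                int perx, int pery, int perz) {
  const int n = pos.nrow();
  const int dims[3] = {nx, ny, nz};
  const int per[3] = {perx, pery, perz};
  for (int k = 0; k < n; ++k) {
    double p[3] = {pos(k,0), pos(k,1), pos(k,2)};
    int i0[3]; double w1[3];
    for (int d = 0; d < 3; ++d) {
      double pd = p[d];
      if (per[d]) {
        pd -= dims[d]*std::floor(pd/dims[d]);
        if (pd >= dims[d]) pd -= dims[d];
      }
      double fl = std::floor(pd);
      i0[d] = (int)fl;
      w1[d] = pd - fl;           // weight of upper neighbour
      if (i0[d] < 0) { i0[d] = 0; w1[d] = 0.0; }
      if (i0[d] > dims[d]-1) { i0[d] = dims[d]-1; w1[d] = 0.0; }
    }
    for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
    for (int dx = 0; dx <= 1; ++dx) {
      int xi = i0[0] + dx, yi = i0[1] + dy, zi = i0[2] + dz;
      if (per[0]) xi = wrapi(xi, nx); else if (xi > nx-1) xi = nx-1;
      if (per[1]) yi = wrapi(yi, ny); else if (yi > ny-1) yi = ny-1;
      if (per[2]) zi = wrapi(zi, nz); else if (zi > nz-1) zi = nz-1;
      const double w = (dx ? w1[0] : 1.0-w1[0]) *
                       (dy ? w1[1] : 1.0-w1[1]) *
                       (dz ? w1[2] : 1.0-w1[2]);
      if (w == 0.0) continue;
      const R_xlen_t c = (R_xlen_t)xi + (R_xlen_t)nx*(yi + (R_xlen_t)ny*zi);
      Fx[c] += w*frc(k,0);
      Fy[c] += w*frc(k,1);
      Fz[c] += w*frc(k,2);
    }
  }
}

// Interpolate up to three grid fields at node positions (hat kernel).
// Pass the same field three times via R wrapper for scalars if wanted.
// [[Rcpp::export]]
NumericMatrix cpp_interp(NumericVector gx, NumericVector gy, NumericVector gz,
                         NumericMatrix pos, int nx, int ny, int nz,
                         int perx, int pery, int perz) {
  const int n = pos.nrow();
  NumericMatrix out(n, 3);
  const int dims[3] = {nx, ny, nz};
  const int per[3] = {perx, pery, perz};
  for (int k = 0; k < n; ++k) {
    double p[3] = {pos(k,0), pos(k,1), pos(k,2)};
    int i0[3]; double w1[3];
    for (int d = 0; d < 3; ++d) {
      double pd = p[d];
      if (per[d]) {
        pd -= dims[d]*std::floor(pd/dims[d]);
        if (pd >= dims[d]) pd -= dims[d];
      }
      double fl = std::floor(pd);
      i0[d] = (int)fl;
      w1[d] = pd - fl;
      if (i0[d] < 0) { i0[d] = 0; w1[d] = 0.0; }
      if (i0[d] > dims[d]-1) { i0[d] = dims[d]-1; w1[d] = 0.0; }
    }
    double ax = 0, ay = 0, az = 0;
    for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
    for (int dx = 0; dx <= 1; ++dx) {
      int xi = i0[0] + dx, yi = i0[1] + dy, zi = i0[2] + dz;
      if (per[0]) xi = wrapi(xi, nx); else if (xi > nx-1) xi = nx-1;
      if (per[1]) yi = wrapi(yi, ny); else if (yi > ny-1) yi = ny-1;
      if (per[2]) zi = wrapi(zi, nz); else if (zi > nz-1) zi = nz-1;
      const double w = (dx ? w1[0] : 1.0-w1[0]) *
                       (dy ? w1[1] : 1.0-w1[1]) *
                       (dz ? w1[2] : 1.0-w1[2]);
      if (w == 0.0) continue;
      const R_xlen_t c = (R_xlen_t)xi + (R_xlen_t)nx*(yi + (R_xlen_t)ny*zi);
      ax += w*gx[c]; ay += w*gy[c]; az += w*gz[c];
    }
    out(k,0) = ax; out(k,1) = ay; out(k,2) = az;
  }
  return out;
}

// Signed dihedral angles across interior edges.
// edges: (i0,i1,iop1,iop2) 0-based; face1 = (i0,i1,iop1), face2 = (i0,iop2,i1),
// both counter-clockwise seen from outside. theta = atan2((n1 x n2).e, n1.n2)
// with e the unit edge vector i0->i1; theta = 0 for coplanar faces.
// [[Rcpp::export]]
NumericVector cpp_dihedral_angles(NumericMatrix verts, IntegerMatrix edges) {
  const int ne = edges.nrow();
  NumericVector th(ne);
  for (int e = 0; e < ne; ++e) {
    const int i0 = edges(e,0), i1 = edges(e,1), i2 = edges(e,2), i3 = edges(e,3);
    double p0[3], p1[3], p2[3], p3[3];
    for (int d = 0; d < 3; ++d) {
      p0[d] = verts(i0,d); p1[d] = verts(i1,d);
      p2[d] = verts(i2,d); p3[d] = verts(i3,d);
    }
    double ev[3] = {p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2]};
    double a1[3] = {p2[0]-p0[0], p2[1]-p0[1], p2[2]-p0[2]};
    double a2[3] = {p3[0]-p0[0], p3[1]-p0[1], p3[2]-p0[2]};
    double n1[3], n2[3];
    cross3(ev, a1, n1);          // face1 normal (outward)
    cross3(a2, ev, n2);          // face2 normal (outward)
    const double ln1 = std::sqrt(dot3(n1,n1)), ln2 = std::sqrt(dot3(n2,n2));
    const double le = std::sqrt(dot3(ev,ev));
    double cx[3];
    cross3(n1, n2, cx);
    const double s = dot3(cx, ev)/(ln1*ln2*le);
    const double cth = dot3(n1, n2)/(ln1*ln2);
    th[e] = std::atan2(s, cth);
  }
  return th;
}

// Analytic membrane forces: gradient of
//   E = sum_f A0_f * [ks/12 (I1^2 + 2 I1 - 2 I2) + ka/12 I2^2]
//     + kB/2 sum_e tan^2((th-th0)/2)            (or quadratic form)
//     + kA (A - A0)^2 / (2 A0) + kV (V - V0)^2 / (2 V0)
// Returns -dE/dx per vertex, plus the energy split and current area/volume.
// rinv: per-face 2x2 inverse reference-shape matrix, columns (r11,r21,r12,r22)
// so that the 3x2 deformation map is Fm = [a1 a2] %*% Rinv.
// [[Rcpp::export]]
List cpp_membrane_forces(NumericMatrix verts, IntegerMatrix faces,
                         NumericMatrix rinv, NumericVector a0,
                         IntegerMatrix edges, NumericVector theta0,
                         double ks, double ka,
                         double kB, int bend_quadratic,
                         double kA, double kV,
                         double A0, double V0) {
  const int nv = verts.nrow(), nf = faces.nrow(), ne = edges.nrow();
  NumericMatrix F(nv, 3);
  double ES = 0.0, EB = 0.0;
  double Atot = 0.0, Vtot = 0.0;

  // ---- pass 1: face geometry, Skalak, accumulate area/volume ----
  std::vector<double> gradA(3*(size_t)nv, 0.0), gradV(3*(size_t)nv, 0.0);
  for (int fi = 0; fi < nf; ++fi) {
    const int v1 = faces(fi,0), v2 = faces(fi,1), v3 = faces(fi,2);
    double x1[3], x2[3], x3[3];
    for (int d = 0; d < 3; ++d) {
      x1[d] = verts(v1,d); x2[d] = verts(v2,d); x3[d] = verts(v3,d);
    }
    double a1[3] = {x2[0]-x1[0], x2[1]-x1[1], x2[2]-x1[2]};
    double a2[3] = {x3[0]-x1[0], x3[1]-x1[1], x3[2]-x1[2]};
    double nrm[3];
    cross3(a1, a2, nrm);
    const double twoA = std::sqrt(dot3(nrm,nrm));
    if (twoA <= 0.0 || !R_finite(twoA))
      stop("degenerate face %d in membrane mesh", fi + 1);
    Atot += 0.5*twoA;
    Vtot += (x1[0]*(x2[1]*x3[2]-x2[2]*x3[1])
           - x1[1]*(x2[0]*x3[2]-x2[2]*x3[0])
           + x1[2]*(x2[0]*x3[1]-x2[1]*x3[0]))/6.0;

    // grad of face area wrt vertices: ((opposite edge) x nhat)/2
    const double inv2A = 1.0/twoA;
    double nh[3] = {nrm[0]*inv2A, nrm[1]*inv2A, nrm[2]*inv2A}; // n/|n|
    double e23[3] = {x2[0]-x3[0], x2[1]-x3[1], x2[2]-x3[2]};
    double e31[3] = {x3[0]-x1[0], x3[1]-x1[1], x3[2]-x1[2]};
    double e12[3] = {x1[0]-x2[0], x1[1]-x2[1], x1[2]-x2[2]};
    double g1[3], g2[3], g3[3];
    cross3(e23, nh, g1); cross3(e31, nh, g2); cross3(e12, nh, g3);
    for (int d = 0; d < 3; ++d) {
      gradA[3*(size_t)v1+d] += 0.5*g1[d];
      gradA[3*(size_t)v2+d] += 0.5*g2[d];
      gradA[3*(size_t)v3+d] += 0.5*g3[d];
    }
    // grad of signed volume
    double c23[3], c31[3], c12[3];
    cross3(x2, x3, c23); cross3(x3, x1, c31); cross3(x1, x2, c12);
    for (int d = 0; d < 3; ++d) {
      gradV[3*(size_t)v1+d] += c23[d]/6.0;
      gradV[3*(size_t)v2+d] += c31[d]/6.0;
      gradV[3*(size_t)v3+d] += c12[d]/6.0;
    }

    if (ks != 0.0 || ka != 0.0) {
      // deformation map columns: fcol1 = a1 r11 + a2 r21, fcol2 = a1 r12 + a2 r22
      const double r11 = rinv(fi,0), r21 = rinv(fi,1),
                   r12 = rinv(fi,2), r22 = rinv(fi,3);
      double f1[3], f2[3];
      for (int d = 0; d < 3; ++d) {
        f1[d] = a1[d]*r11 + a2[d]*r21;
        f2[d] = a1[d]*r12 + a2[d]*r22;
      }
      const double g11 = dot3(f1,f1), g22 = dot3(f2,f2), g12 = dot3(f1,f2);
      const double I1 = g11 + g22 - 2.0;
      const double detG = g11*g22 - g12*g12;
      const double I2 = detG - 1.0;
      const double w = ks/12.0*(I1*I1 + 2.0*I1 - 2.0*I2) + ka/12.0*I2*I2;
      ES += a0[fi]*w;
      const double wI1 = ks/12.0*(2.0*I1 + 2.0);
      const double wI2 = -ks/6.0 + ka/6.0*I2;
      // dw/dF = 2 wI1 F + 2 wI2 F adj(G); adj(G) = [[g22,-g12],[-g12,g11]]
      double P1[3], P2[3];
      for (int d = 0; d < 3; ++d) {
        const double Fa1 = f1[d]*g22 - f2[d]*g12;   // (F adjG) col1
        const double Fa2 = -f1[d]*g12 + f2[d]*g11;  // (F adjG) col2
        P1[d] = 2.0*wI1*f1[d] + 2.0*wI2*Fa1;
        P2[d] = 2.0*wI1*f2[d] + 2.0*wI2*Fa2;
      }
      // dE/da1 = A0 (P1 r11 + P2 r12), dE/da2 = A0 (P1 r21 + P2 r22)
      for (int d = 0; d < 3; ++d) {
        const double dEa1 = a0[fi]*(P1[d]*r11 + P2[d]*r12);
        const double dEa2 = a0[fi]*(P1[d]*r21 + P2[d]*r22);
        F(v2,d) -= dEa1;
        F(v3,d) -= dEa2;
        F(v1,d) += dEa1 + dEa2;
      }
    }
  }

  // ---- global area / volume constraint forces ----
  const double dA = Atot - A0, dV = Vtot - V0;
  const double EA = (kA != 0.0) ? 0.5*kA*dA*dA/A0 : 0.0;
  const double EV = (kV != 0.0) ? 0.5*kV*dV*dV/V0 : 0.0;
  if (kA != 0.0 || kV != 0.0) {
    const double cA = kA*dA/A0, cV = kV*dV/V0;
    for (int v = 0; v < nv; ++v)
      for (int d = 0; d < 3; ++d)
        F(v,d) -= cA*gradA[3*(size_t)v+d] + cV*gradV[3*(size_t)v+d];
  }

  // ---- bending ----
  if (kB != 0.0) {
    for (int e = 0; e < ne; ++e) {
      const int i0 = edges(e,0), i1 = edges(e,1), i2 = edges(e,2), i3 = edges(e,3);
      double p0[3], p1[3], p2[3], p3[3];
      for (int d = 0; d < 3; ++d) {
        p0[d] = verts(i0,d); p1[d] = verts(i1,d);
        p2[d] = verts(i2,d); p3[d] = verts(i3,d);
      }
      double ev[3] = {p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2]};
      double b1[3] = {p2[0]-p0[0], p2[1]-p0[1], p2[2]-p0[2]};
      double b2[3] = {p3[0]-p0[0], p3[1]-p0[1], p3[2]-p0[2]};
      double n1[3], n2[3];
      cross3(ev, b1, n1);
      cross3(b2, ev, n2);
      const double n1sq = dot3(n1,n1), n2sq = dot3(n2,n2);
      const double le = std::sqrt(dot3(ev,ev));
      double cx[3];
      cross3(n1, n2, cx);
      const double s = dot3(cx, ev)/(std::sqrt(n1sq*n2sq)*le);
      const double cth = dot3(n1,n2)/std::sqrt(n1sq*n2sq);
      const double th = std::atan2(s, cth);
      const double dth = th - theta0[e];
      double dEdth;
      if (bend_quadratic) {
        EB += 0.5*kB*dth*dth;
        dEdth = kB*dth;
      } else {
        const double t = std::tan(0.5*dth);
        if (!R_finite(t) || std::fabs(t) > 1e6)
          stop("bending angle at edge %d approached the tan singularity", e + 1);
        EB += 0.5*kB*t*t;
        dEdth = 0.5*kB*t*(1.0 + t*t);
      }
      // dihedral-angle gradients (discrete-shells form)
      const double inve = 1.0/le;
      const double c01 = dot3(b1, ev)*inve;           // (p2-p0).e^
      const double c02 = dot3(b2, ev)*inve;           // (p3-p0).e^
      double d21[3] = {p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2]};
      double d31[3] = {p3[0]-p1[0], p3[1]-p1[1], p3[2]-p1[2]};
      const double c11 = dot3(d21, ev)*inve;          // (p2-p1).e^
      const double c12 = dot3(d31, ev)*inve;          // (p3-p1).e^
      for (int d = 0; d < 3; ++d) {
        const double h1 = n1[d]/n1sq, h2 = n2[d]/n2sq;
        const double g2 = le*h1;            // d th / d p2
        const double g3 = le*h2;            // d th / d p3
        const double g0 = c11*h1 + c12*h2;  // d th / d p0
        const double g1 = -c01*h1 - c02*h2; // d th / d p1
        F(i2,d) += dEdth*g2;
        F(i3,d) += dEdth*g3;
        F(i0,d) += dEdth*g0;
        F(i1,d) += dEdth*g1;
      }
    }
  }

  return List::create(_["forces"] = F,
                      _["E_S"] = ES, _["E_B"] = EB,
                      _["E_A"] = EA, _["E_V"] = EV,
                      _["area"] = Atot, _["volume"] = Vtot);
}
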