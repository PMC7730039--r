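// Element kernels for the axisymmetric (r, z) poroelastic solver.
//
// Conventions used throughout:
//  - bilinear 4-node quadrilaterals, counter-clockwise connectivity;
//  - strain vector [e_rr, e_zz, e_tt, g_rz] with engineering shear g_rz;
//  - volume integrals carry the axisymmetric weight r (the common 2*pi is
//    dropped consistently from stiffness and loads, so solutions are
//    unaffected); a planar weighting (w = 1) is available for fixtures;
//  - units: mm, MPa (N/mm^2), permeability in mm^4/(N s).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GP = 0.577350269189625764509148780502; // 1/sqrt(3)

struct ShapeEval {
  double N[4];
  double dNdr[4];
  double dNdz[4];
  double detJ;
  double r;
};

// Evaluate bilinear shape functions and their physical derivatives at
// (xi, eta) for an element with corner coordinates (r[4], z[4]).
static bool shape_eval(const double* r, const double* z,
                       double xi, double eta, ShapeEval& out) {
  double N[4]  = {0.25 * (1 - xi) * (1 - eta), 0.25 * (1 + xi) * (1 - eta),
                  0.25 * (1 + xi) * (1 + eta), 0.25 * (1 - xi) * (1 + eta)};
  double dNxi[4]  = {-0.25 * (1 - eta),  0.25 * (1 - eta),
                      0.25 * (1 + eta), -0.25 * (1 + eta)};
  double dNeta[4] = {-0.25 * (1 - xi), -0.25 * (1 + xi),
                      0.25 * (1 + xi),  0.25 * (1 - xi)};
  double Jrr = 0, Jrz = 0, Jzr = 0, Jzz = 0; // d(r,z)/d(xi,eta)
  for (int a = 0; a < 4; ++a) {
    Jrr += dNxi[a]  * r[a]; Jrz += dNxi[a]  * z[a];
    Jzr += dNeta[a] * r[a]; Jzz += dNeta[a] * z[a];
  }
  double det = Jrr * Jzz - Jrz * Jzr;
  if (det <= 0) return false;
  double iJrr =  Jzz / det, iJrz = -Jrz / det;
  double iJzr = -Jzr / det, iJzz =  Jrr / det;
  out.detJ = det;
  out.r = 0;
  for (int a = 0; a < 4; ++a) {
    out.N[a] = N[a];
    out.dNdr[a] = iJrr * dNxi[a] + iJrz * dNeta[a];
    out.dNdz[a] = iJzr * dNxi[a] + iJzz * dNeta[a];
    out.r += N[a] * r[a];
  }
  return true;
}

// Assemble element contributions for the coupled u-p system.
//
// nodes:  n x 2 (r, z); elems: m x 4 one-based connectivity.
// E, nu:  drained Young's modulus (MPa) and Poisson ratio per element.
// perm:   hydraulic mobility k (mm^4 / (N s)) per element; ignored when
//         poro[e] is FALSE (solid-only elements contribute stiffness only).
// axisym: TRUE for r-weighted integrals, FALSE for planar fixtures.
//
// Returns triplets for K (2n x 2n, dof order ur_1, uz_1, ur_2, ...),
// Q (2n x n) the coupling matrix  int B' m N_p w, H (n x n) the
// permeability matrix, a lumped "mass" vector Mlump (int N w, row-sum
// lumping of the consistent mass), and per-element in-plane areas.
// [[Rcpp::export(name = ".assemble_axisym")]]
List assemble_axisym(NumericMatrix nodes, IntegerMatrix elems,
                     NumericVector E, NumericVector nu, NumericVector perm,
                     LogicalVector poro, bool axisym = true) {
  const int m = elems.nrow();
  const int n = nodes.nrow();
  const int kK = 64, kQ = 32, kH = 16;
  IntegerVector Ki(m * kK), Kj(m * kK);
  NumericVector Kx(m * kK);
  IntegerVector Qi(m * kQ), Qj(m * kQ);
  NumericVector Qx(m * kQ);
  IntegerVector Hi(m * kH), Hj(m * kH);
  NumericVector Hx(m * kH);
  NumericVector Mlump(n);
  NumericVector area(m);
  const double gp[2] = {-GP, GP};

  for (int e = 0; e < m; ++e) {
    double r[4], z[4];
    int nd[4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = elems(e, a) - 1;
      r[a] = nodes(nd[a], 0);
      z[a] = nodes(nd[a], 1);
    }
    const double Ee = E[e], nue = nu[e];
    const double lam = Ee * nue / ((1 + nue) * (1 - 2 * nue));
    const double G = Ee / (2 * (1 + nue));
    const double d00 = lam + 2 * G;
    double Ke[8][8] = {{0}}, Qe[8][4] = {{0}}, He[4][4] = {{0}}, Me[4] = {0};
    double ae = 0;
    bool ok = true;
    for (int gi = 0; gi < 2 && ok; ++gi) {
      for (int gj = 0; gj < 2 && ok; ++gj) {
        ShapeEval s;
        if (!shape_eval(r, z, gp[gi], gp[gj], s)) { ok = false; break; }
        const double w = s.detJ * (axisym ? s.r : 1.0);
        ae += s.detJ;
        // B rows: e_rr, e_zz, e_tt, g_rz ; columns ur_a, uz_a
        double B[4][8] = {{0}};
        for (int a = 0; a < 4; ++a) {
          B[0][2 * a]     = s.dNdr[a];
          B[1][2 * a + 1] = s.dNdz[a];
          B[2][2 * a]     = axisym ? (s.N[a] / s.r) : 0.0;
          B[3][2 * a]     = s.dNdz[a];
          B[3][2 * a + 1] = s.dNdr[a];
        }
        for (int i = 0; i < 8; ++i) {
          // DB for column i
          double db0 = d00 * B[0][i] + lam * B[1][i] + lam * B[2][i];
          double db1 = lam * B[0][i] + d00 * B[1][i] + lam * B[2][i];
          double db2 = lam * B[0][i] + lam * B[1][i] + d00 * B[2][i];
          double db3 = G * B[3][i];
          for (int j = 0; j < 8; ++j)
            Ke[j][i] += (B[0][j] * db0 + B[1][j] * db1 +
                         B[2][j] * db2 + B[3][j] * db3) * w;
          double bvol = B[0][i] + B[1][i] + B[2][i];
          for (int j = 0; j < 4; ++j) Qe[i][j] += bvol * s.N[j] * w;
        }
        if (poro[e]) {
          for (int a = 0; a < 4; ++a) {
            for (int b = 0; b < 4; ++b)
              He[a][b] += perm[e] *
                (s.dNdr[a] * s.dNdr[b] + s.dNdz[a] * s.dNdz[b]) * w;
            Me[a] += s.N[a] * w;
          }
        }
      }
    }
    if (!ok) stop("element %d has a non-positive Jacobian", e + 1);
    area[e] = ae;
    int off = e * kK;
    for (int a = 0; a < 4; ++a)
      for (int ia = 0; ia < 2; ++ia)
        for (int b = 0; b < 4; ++b)
          for (int ib = 0; ib < 2; ++ib) {
            int idx = off + (2 * a + ia) * 8 + 2 * b + ib;
            Ki[idx] = 2 * nd[a] + ia + 1;
            Kj[idx] = 2 * nd[b] + ib + 1;
            Kx[idx] = Ke[2 * a + ia][2 * b + ib];
          }
    off = e * kQ;
    for (int a = 0; a < 4; ++a)
      for (int ia = 0; ia < 2; ++ia)
        for (int b = 0; b < 4; ++b) {
          int idx = off + (2 * a + ia) * 4 + b;
          Qi[idx] = 2 * nd[a] + ia + 1;
          Qj[idx] = nd[b] + 1;
          Qx[idx] = poro[e] ? Qe[2 * a + ia][b] : 0.0;
        }
    off = e * kH;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        int idx = off + a * 4 + b;
        Hi[idx] = nd[a] + 1;
        Hj[idx] = nd[b] + 1;
        Hx[idx] = He[a][b];
      }
    if (poro[e]) for (int a = 0; a < 4; ++a) Mlump[nd[a]] += Me[a];
  }
  return List::create(
    _["Ki"] = Ki, _["Kj"] = Kj, _["Kx"] = Kx,
    _["Qi"] = Qi, _["Qj"] = Qj, _["Qx"] = Qx,
    _["Hi"] = Hi, _["Hj"] = Hj, _["Hx"] = Hx,
    _["Mlump"] = Mlump, _["area"] = area);
}

// Scalar-field (diffusion) element matrices: stiffness int grad N . grad N w
// and lumped mass int N w over the given elements.
// [[Rcpp::export(name = ".assemble_scalar")]]
List assemble_scalar(NumericMatrix nodes, IntegerMatrix elems,
                     bool axisym = true) {
  const int m = elems.nrow();
  const int n = nodes.nrow();
  IntegerVector Ai(m * 16), Aj(m * 16);
  NumericVector Ax(m * 16);
  NumericVector Mlump(n);
  const double gp[2] = {-GP, GP};
  for (int e = 0; e < m; ++e) {
    double r[4], z[4];
    int nd[4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = elems(e, a) - 1;
      r[a] = nodes(nd[a], 0);
      z[a] = nodes(nd[a], 1);
    }
    double Ae[4][4] = {{0}}, Me[4] = {0};
    for (int gi = 0; gi < 2; ++gi)
      for (int gj = 0; gj < 2; ++gj) {
        ShapeEval s;
        if (!shape_eval(r, z, gp[gi], gp[gj], s))
          stop("element %d has a non-positive Jacobian", e + 1);
        const double w = s.detJ * (axisym ? s.r : 1.0);
        for (int a = 0; a < 4; ++a) {
          for (int b = 0; b < 4; ++b)
            Ae[a][b] += (s.dNdr[a] * s.dNdr[b] + s.dNdz[a] * s.dNdz[b]) * w;
          Me[a] += s.N[a] * w;
        }
      }
    for (int a = 0; a < 4; ++a) {
      Mlump[nd[a]] += Me[a];
      for (int b = 0; b < 4; ++b) {
        int idx = e * 16 + a * 4 + b;
        Ai[idx] = nd[a] + 1;
        Aj[idx] = nd[b] + 1;
        Ax[idx] = Ae[a][b];
      }
    }
  }
  return List::create(_["Ai"] = Ai, _["Aj"] = Aj, _["Ax"] = Ax,
                      _["Mlump"] = Mlump);
}

// Per-element strain vector [e_rr, e_zz, e_tt, g_rz] at the element
// centroid (xi = eta = 0) from a nodal displacement field u (2n, ur/uz
// interleaved).
// [[Rcpp::export(name = ".element_strain_centroid")]]
NumericMatrix element_strain_centroid(NumericMatrix nodes, IntegerMatrix elems,
                                      NumericVector u, bool axisym = true) {
  const int m = elems.nrow();
  NumericMatrix out(m, 4);
  for (int e = 0; e < m; ++e) {
    double r[4], z[4], ur[4], uz[4];
    for (int a = 0; a < 4; ++a) {
      int nd = elems(e, a) - 1;
      r[a] = nodes(nd, 0);
      z[a] = nodes(nd, 1);
      ur[a] = u[2 * nd];
      uz[a] = u[2 * nd + 1];
    }
    ShapeEval s;
    if (!shape_eval(r, z, 0.0, 0.0, s))
      stop("element %d has a non-positive Jacobian", e + 1);
    double err = 0, ezz = 0, ett = 0, grz = 0;
    for (int a = 0; a < 4; ++a) {
      err += s.dNdr[a] * ur[a];
      ezz += s.dNdz[a] * uz[a];
      if (axisym) ett += s.N[a] * ur[a] / s.r;
      grz += s.dNdz[a] * ur[a] + s.dNdr[a] * uz[a];
    }
    out(e, 0) = err; out(e, 1) = ezz; out(e, 2) = ett; out(e, 3) = grz;
  }
  return out;
}

// Per-element gradient of a nodal scalar field at the element centroid.
// [[Rcpp::export(name = ".element_grad_centroid")]]
NumericMatrix element_grad_centroid(NumericMatrix nodes, IntegerMatrix elems,
                                    NumericVector p) {
  const int m = elems.nrow();
  NumericMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    double r[4], z[4], pe[4];
    for (int a = 0; a < 4; ++a) {
      int nd = elems(e, a) - 1;
      r[a] = nodes(nd, 0);
      z[a] = nodes(nd, 1);
      pe[a] = p[nd];
    }
    ShapeEval s;
    if (!shape_eval(r, z, 0.0, 0.0, s))
      stop("element %d has a non-positive Jacobian", e + 1);
    double gr = 0, gz = 0;
    for (int a = 0; a < 4; ++a) {
      gr += s.dNdr[a] * pe[a];
      gz += s.dNdz[a] * pe[a];
    }
    out(e, 0) = gr; out(e, 1) = gz;
  }
  return out;
}

// Minimum Jacobian determinant over the 2x2 Gauss points of each element.
// [[Rcpp::export(name = ".element_min_jacobian")]]
NumericVector element_min_jacobian(NumericMatrix nodes, IntegerMatrix elems) {
  const int m = elems.nrow();
  NumericVector out(m);
  const double gp[2] = {-GP, GP};
  for (int e = 0; e < m; ++e) {
    double r[4], z[4];
    for (int a = 0; a < 4; ++a) {
      int nd = elems(e, a) - 1;
      r[a] = nodes(nd, 0);
      z[a] = nodes(nd, 1);
    }
    double mn = R_PosInf;
    for (int gi = 0; gi < 2; ++gi)
      for (int gj = 0; gj < 2; ++gj) {
        ShapeEval s;
        double det;
        if (!shape_eval(r, z, gp[gi], gp[gj], s)) det = -1.0; else det = s.detJ;
        if (det < mn) mn = det;
      }
    out[e] = mn;
  }
  return out;
}
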