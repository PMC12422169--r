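#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 10-node tetrahedron kernels (small-strain isotropic elasticity).
// Elements are affine (mid-edge nodes at edge midpoints), so the Jacobian is
// computed from the corner nodes and is constant over the element.

static const double GP_A = 0.585410196624969;
static const double GP_B = 0.138196601125011;

// VTK tet10 edge ordering: nodes 5..10 sit on these corner pairs
static const int ED[6][2] = {{0, 1}, {1, 2}, {2, 0}, {0, 3}, {1, 3}, {2, 3}};

struct ElemGeom {
  double grad[4][3]; // gradients of barycentric coords
  double V;          // signed volume
};

static bool elem_geom(const double *x, const double *y, const double *z,
                      ElemGeom &g) {
  double a[3][3];
  for (int i = 0; i < 3; ++i) {
    a[0][i] = 0.0;
  }
  a[0][0] = x[1] - x[0]; a[0][1] = y[1] - y[0]; a[0][2] = z[1] - z[0];
  a[1][0] = x[2] - x[0]; a[1][1] = y[2] - y[0]; a[1][2] = z[2] - z[0];
  a[2][0] = x[3] - x[0]; a[2][1] = y[3] - y[0]; a[2][2] = z[3] - z[0];
  double det = a[0][0] * (a[1][1] * a[2][2] - a[1][2] * a[2][1]) -
               a[0][1] * (a[1][0] * a[2][2] - a[1][2] * a[2][0]) +
               a[0][2] * (a[1][0] * a[2][1] - a[1][1] * a[2][0]);
  g.V = det / 6.0;
  if (det <= 0.0) return false;
  double inv[3][3];
  inv[0][0] =  (a[1][1] * a[2][2] - a[1][2] * a[2][1]) / det;
  inv[0][1] = -(a[0][1] * a[2][2] - a[0][2] * a[2][1]) / det;
  inv[0][2] =  (a[0][1] * a[1][2] - a[0][2] * a[1][1]) / det;
  inv[1][0] = -(a[1][0] * a[2][2] - a[1][2] * a[2][0]) / det;
  inv[1][1] =  (a[0][0] * a[2][2] - a[0][2] * a[2][0]) / det;
  inv[1][2] = -(a[0][0] * a[1][2] - a[0][2] * a[1][0]) / det;
  inv[2][0] =  (a[1][0] * a[2][1] - a[1][1] * a[2][0]) / det;
  inv[2][1] = -(a[0][0] * a[2][1] - a[0][1] * a[2][0]) / det;
  inv[2][2] =  (a[0][0] * a[1][1] - a[0][1] * a[1][0]) / det;
  // x = p1 + J^T (l2,l3,l4), so grad(lambda_{i+1}) = column i of inv(J);
  // lambda_1 = 1 - sum
  for (int d = 0; d < 3; ++d) {
    g.grad[1][d] = inv[d][0];
    g.grad[2][d] = inv[d][1];
    g.grad[3][d] = inv[d][2];
    g.grad[0][d] = -(inv[d][0] + inv[d][1] + inv[d][2]);
  }
  return true;
}

// shape-function gradients (10 x 3) at barycentric point lam
static void shape_grads(const ElemGeom &g, const double lam[4],
                        double dN[10][3]) {
  for (int i = 0; i < 4; ++i)
    for (int d = 0; d < 3; ++d)
      dN[i][d] = (4.0 * lam[i] - 1.0) * g.grad[i][d];
  for (int e = 0; e < 6; ++e) {
    int a = ED[e][0], b = ED[e][1];
    for (int d = 0; d < 3; ++d)
      dN[4 + e][d] = 4.0 * (lam[a] * g.grad[b][d] + lam[b] * g.grad[a][d]);
  }
}

static void dmat(double E, double nu, double D[6][6]) {
  double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  double mu = E / (2.0 * (1.0 + nu));
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) D[i][j] = 0.0;
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D[i][j] = lam;
    D[i][i] = lam + 2.0 * mu;
    D[3 + i][3 + i] = mu;
  }
}

// strain-displacement rows for node n: contributes to strains
// (exx, eyy, ezz, gxy, gyz, gzx)
static inline void bn(const double dn[3], double B[6][3]) {
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 3; ++j) B[i][j] = 0.0;
  B[0][0] = dn[0];
  B[1][1] = dn[1];
  B[2][2] = dn[2];
  B[3][0] = dn[1]; B[3][1] = dn[0];
  B[4][1] = dn[2]; B[4][2] = dn[1];
  B[5][0] = dn[2]; B[5][2] = dn[0];
}

static void element_stiffness(const double *x, const double *y, const double *z,
                              double E, double nu, double ke[30][30],
                              bool &ok) {
  ElemGeom g;
  ok = elem_geom(x, y, z, g);
  if (!ok) return;
  double D[6][6];
  dmat(E, nu, D);
  for (int i = 0; i < 30; ++i)
    for (int j = 0; j < 30; ++j) ke[i][j] = 0.0;
  double lam[4], dN[10][3];
  for (int gp = 0; gp < 4; ++gp) {
    for (int i = 0; i < 4; ++i) lam[i] = GP_B;
    lam[gp] = GP_A;
    shape_grads(g, lam, dN);
    double w = g.V / 4.0;
    // accumulate B' D B * w
    double Ba[6][3], Bb[6][3], DB[6][3];
    for (int a = 0; a < 10; ++a) {
      bn(dN[a], Ba);
      for (int b = a; b < 10; ++b) {
        bn(dN[b], Bb);
        for (int i = 0; i < 6; ++i)
          for (int j = 0; j < 3; ++j) {
            double s = 0.0;
            for (int k = 0; k < 6; ++k) s += D[i][k] * Bb[k][j];
            DB[i][j] = s;
          }
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double s = 0.0;
            for (int k = 0; k < 6; ++k) s += Ba[k][i] * DB[k][j];
            ke[3 * a + i][3 * b + j] += w * s;
          }
      }
    }
  }
  // mirror upper block triangle to lower
  for (int a = 0; a < 10; ++a)
    for (int b = a; b < 10; ++b)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          ke[3 * b + j][3 * a + i] = ke[3 * a + i][3 * b + j];
}

static void gather(const NumericMatrix &nodes, const IntegerMatrix &elems,
                   int e, double *x, double *y, double *z, int *nid) {
  for (int a = 0; a < 10; ++a) {
    int n = elems(e, a) - 1;
    nid[a] = n;
    x[a] = nodes(n, 0);
    y[a] = nodes(n, 1);
    z[a] = nodes(n, 2);
  }
}

// [[Rcpp::export]]
List tet10_stiffness_triplets(NumericMatrix nodes, IntegerMatrix elems,
                              NumericVector E, NumericVector nu) {
  int m = elems.nrow();
  R_xlen_t per = 465; // lower triangle of 30x30
  IntegerVector I(per * m), J(per * m);
  NumericVector X(per * m);
  double x[10], y[10], z[10], ke[30][30];
  int nid[10];
  R_xlen_t p = 0;
  for (int e = 0; e < m; ++e) {
    gather(nodes, elems, e, x, y, z, nid);
    bool ok;
    element_stiffness(x, y, z, E[e], nu[e], ke, ok);
    if (!ok) stop("degenerate element (non-positive Jacobian) at index %d", e + 1);
    int dof[30];
    for (int a = 0; a < 10; ++a)
      for (int d = 0; d < 3; ++d) dof[3 * a + d] = 3 * nid[a] + d + 1;
    for (int i = 0; i < 30; ++i)
      for (int j = 0; j <= i; ++j) {
        int di = dof[i], dj = dof[j];
        if (di >= dj) { I[p] = di; J[p] = dj; }
        else          { I[p] = dj; J[p] = di; }
        X[p] = ke[i][j];
        ++p;
      }
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = X);
}

// assembled internal nodal forces sum_e k_e u_e, returned as N x 3
// [[Rcpp::export]]
NumericMatrix tet10_internal_forces(NumericMatrix nodes, IntegerMatrix elems,
                                    NumericVector E, NumericVector nu,
                                    NumericMatrix U) {
  int m = elems.nrow(), n = nodes.nrow();
  NumericMatrix F(n, 3);
  double x[10], y[10], z[10], ke[30][30], ue[30], fe[30];
  int nid[10];
  for (int e = 0; e < m; ++e) {
    gather(nodes, elems, e, x, y, z, nid);
    bool ok;
    element_stiffness(x, y, z, E[e], nu[e], ke, ok);
    if (!ok) stop("degenerate element at index %d", e + 1);
    for (int a = 0; a < 10; ++a)
      for (int d = 0; d < 3; ++d) ue[3 * a + d] = U(nid[a], d);
    for (int i = 0; i < 30; ++i) {
      double s = 0.0;
      for (int j = 0; j < 30; ++j) s += ke[i][j] * ue[j];
      fe[i] = s;
    }
    for (int a = 0; a < 10; ++a)
      for (int d = 0; d < 3; ++d) F(nid[a], d) += fe[3 * a + d];
  }
  return F;
}

// eigenvalues of a symmetric 3x3 (analytic, descending)
static void eig3(const double s[6], double ev[3]) {
  // s = (xx, yy, zz, xy, yz, zx)
  double p1 = s[3] * s[3] + s[4] * s[4] + s[5] * s[5];
  double q = (s[0] + s[1] + s[2]) / 3.0;
  if (p1 < 1e-300) {
    ev[0] = s[0]; ev[1] = s[1]; ev[2] = s[2];
  } else {
    double b0 = s[0] - q, b1 = s[1] - q, b2 = s[2] - q;
    double p2 = b0 * b0 + b1 * b1 + b2 * b2 + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    // det of (S - q I)/p
    double a00 = b0 / p, a11 = b1 / p, a22 = b2 / p;
    double a01 = s[3] / p, a12 = s[4] / p, a02 = s[5] / p;
    double detB = a00 * (a11 * a22 - a12 * a12) -
                  a01 * (a01 * a22 - a12 * a02) +
                  a02 * (a01 * a12 - a11 * a02);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    ev[0] = q + 2.0 * p * std::cos(phi);
    ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[1] = 3.0 * q - ev[0] - ev[2];
  }
  // sort descending
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (ev[j] > ev[i]) { double t = ev[i]; ev[i] = ev[j]; ev[j] = t; }
}

// per-element stresses at the 4 quadrature points plus principal summaries
// [[Rcpp::export]]
List tet10_stresses(NumericMatrix nodes, IntegerMatrix elems, NumericVector E,
                    NumericVector nu, NumericMatrix U) {
  int m = elems.nrow();
  NumericMatrix S(m, 24);    // 4 gp x 6 comps
  NumericMatrix Smean(m, 6); // volume-average
  NumericVector maxp(m), minp(m), vmax(m);
  double x[10], y[10], z[10], ue[30];
  int nid[10];
  double lam[4], dN[10][3], D[6][6];
  for (int e = 0; e < m; ++e) {
    gather(nodes, elems, e, x, y, z, nid);
    ElemGeom g;
    if (!elem_geom(x, y, z, g)) stop("degenerate element at index %d", e + 1);
    dmat(E[e], nu[e], D);
    for (int a = 0; a < 10; ++a)
      for (int d = 0; d < 3; ++d) ue[3 * a + d] = U(nid[a], d);
    double mp = -1e300, mn = 1e300, vm = 0.0;
    for (int gp = 0; gp < 4; ++gp) {
      for (int i = 0; i < 4; ++i) lam[i] = GP_B;
      lam[gp] = GP_A;
      shape_grads(g, lam, dN);
      double eps[6] = {0, 0, 0, 0, 0, 0};
      for (int a = 0; a < 10; ++a) {
        double ux = ue[3 * a], uy = ue[3 * a + 1], uz = ue[3 * a + 2];
        eps[0] += dN[a][0] * ux;
        eps[1] += dN[a][1] * uy;
        eps[2] += dN[a][2] * uz;
        eps[3] += dN[a][1] * ux + dN[a][0] * uy;
        eps[4] += dN[a][2] * uy + dN[a][1] * uz;
        eps[5] += dN[a][2] * ux + dN[a][0] * uz;
      }
      double sig[6];
      for (int i = 0; i < 6; ++i) {
        double s = 0.0;
        for (int j = 0; j < 6; ++j) s += D[i][j] * eps[j];
        sig[i] = s;
        S(e, 6 * gp + i) = s;
        Smean(e, i) += s / 4.0;
      }
      double ev[3];
      eig3(sig, ev);
      if (ev[0] > mp) mp = ev[0];
      if (ev[2] < mn) mn = ev[2];
      double dv = std::sqrt(0.5 * ((ev[0] - ev[1]) * (ev[0] - ev[1]) +
                                   (ev[1] - ev[2]) * (ev[1] - ev[2]) +
                                   (ev[2] - ev[0]) * (ev[2] - ev[0])));
      if (dv > vm) vm = dv;
    }
    maxp[e] = mp;
    minp[e] = mn;
    vmax[e] = vm;
  }
  return List::create(_["gp"] = S, _["mean"] = Smean,
                      _["max_principal"] = maxp, _["min_principal"] = minp,
                      _["von_mises"] = vmax);
}

// signed corner volumes
// [[Rcpp::export]]
NumericVector tet10_volumes(NumericMatrix nodes, IntegerMatrix elems) {
  int m = elems.nrow();
  NumericVector V(m);
  double x[10], y[10], z[10];
  int nid[10];
  for (int e = 0; e < m; ++e) {
    gather(nodes, elems, e, x, y, z, nid);
    ElemGeom g;
    elem_geom(x, y, z, g);
    V[e] = g.V;
  }
  return V;
}
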