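// Element kernels for 10-node quadratic tetrahedra, small-strain isotropic
// elasticity with per-element eigenstrain. Straight-sided elements only:
// barycentric gradients are constant, so a degree-2 Gauss rule is exact.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// edge pairs for nodes 5..10 (1-based corner ids)
const int EDGE[6][2] = {{1, 2}, {2, 3}, {1, 3}, {1, 4}, {2, 4}, {3, 4}};

// 4-point Gauss rule on the reference tet (degree 2)
const double GA = 0.5854101966249685;
const double GB = 0.1381966011250105;

void elem_geometry(const arma::mat &X, arma::mat &gL, double &vol) {
  // X: 4 x 3 corner coordinates; gL: 4 x 3 barycentric gradients
  arma::mat M(4, 4);
  for (int i = 0; i < 4; ++i) {
    M(0, i) = 1.0;
    M(1, i) = X(i, 0);
    M(2, i) = X(i, 1);
    M(3, i) = X(i, 2);
  }
  double detM = arma::det(M);
  vol = detM / 6.0;
  arma::mat Minv = arma::inv(M);
  gL = Minv.cols(1, 3); // row k = grad L_k
}

// B matrix (6 x 30) at barycentric point L; Voigt (xx,yy,zz,yz,xz,xy),
// engineering shear strains
void bmatrix(const arma::vec &L, const arma::mat &gL, arma::mat &B) {
  B.zeros(6, 30);
  arma::mat dN(10, 3);
  for (int i = 0; i < 4; ++i)
    dN.row(i) = (4.0 * L(i) - 1.0) * gL.row(i);
  for (int e = 0; e < 6; ++e) {
    int a = EDGE[e][0] - 1, b = EDGE[e][1] - 1;
    dN.row(4 + e) = 4.0 * (L(a) * gL.row(b) + L(b) * gL.row(a));
  }
  for (int n = 0; n < 10; ++n) {
    double gx = dN(n, 0), gy = dN(n, 1), gz = dN(n, 2);
    int c = 3 * n;
    B(0, c) = gx;
    B(1, c + 1) = gy;
    B(2, c + 2) = gz;
    B(3, c + 1) = gz; B(3, c + 2) = gy;
    B(4, c) = gz;     B(4, c + 2) = gx;
    B(5, c) = gy;     B(5, c + 1) = gx;
  }
}

arma::mat cmatrix(double E, double nu) {
  double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  double mu = E / (2.0 * (1.0 + nu));
  arma::mat C(6, 6, arma::fill::zeros);
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) C(i, j) = lam;
    C(i, i) = lam + 2.0 * mu;
    C(i + 3, i + 3) = mu;
  }
  return C;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".fem_assemble")]]
List fem_assemble(const arma::mat &nodes, const arma::imat &elems,
                  const arma::vec &Emod, const arma::vec &nu,
                  const arma::mat &eig) {
  const int ne = elems.n_rows;
  const int nn = nodes.n_rows;
  const R_xlen_t ntrip = (R_xlen_t)ne * 465; // lower triangle of 30x30
  IntegerVector ti(ntrip), tj(ntrip);
  NumericVector tv(ntrip);
  NumericVector f(3 * (R_xlen_t)nn);
  NumericVector vols(ne);

  arma::mat gauss(4, 4);
  gauss.fill(GB);
  for (int g = 0; g < 4; ++g) gauss(g, g) = GA;

  arma::mat X(4, 3), gL, B, Ke(30, 30), C;
  arma::vec fe(30), L(4), estar(6);
  arma::ivec gdof(30);
  R_xlen_t pos = 0;

  for (int e = 0; e < ne; ++e) {
    for (int i = 0; i < 4; ++i)
      for (int d = 0; d < 3; ++d) X(i, d) = nodes(elems(e, i) - 1, d);
    double vol;
    elem_geometry(X, gL, vol);
    if (vol <= 0.0) stop("element %d has non-positive volume", e + 1);
    vols[e] = vol;
    C = cmatrix(Emod(e), nu(e));
    estar = eig.row(e).t();
    Ke.zeros();
    fe.zeros();
    double w = vol / 4.0;
    for (int g = 0; g < 4; ++g) {
      L = gauss.row(g).t();
      bmatrix(L, gL, B);
      Ke += w * (B.t() * C * B);
      fe += w * (B.t() * (C * estar));
    }
    for (int n = 0; n < 10; ++n)
      for (int d = 0; d < 3; ++d)
        gdof(3 * n + d) = 3 * (elems(e, n) - 1) + d; // 0-based
    for (int p = 0; p < 30; ++p) {
      f[gdof(p)] += fe(p);
      for (int q = 0; q <= p; ++q) {
        int gi = gdof(p), gj = gdof(q);
        if (gi >= gj) {
          ti[pos] = gi + 1; tj[pos] = gj + 1;
        } else {
          ti[pos] = gj + 1; tj[pos] = gi + 1;
        }
        tv[pos] = Ke(p, q);
        ++pos;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["v"] = tv, _["f"] = f,
                      _["vol"] = vols);
}

//' @noRd
// [[Rcpp::export(name = ".fem_element_stress")]]
arma::mat fem_element_stress(const arma::mat &nodes, const arma::imat &elems,
                             const arma::vec &Emod, const arma::vec &nu,
                             const arma::mat &eig, const arma::vec &u) {
  const int ne = elems.n_rows;
  arma::mat out(ne, 6);
  arma::mat X(4, 3), gL, B, C;
  arma::vec L(4);
  L.fill(0.25); // centroid
  arma::vec ue(30), eps(6);
  for (int e = 0; e < ne; ++e) {
    for (int i = 0; i < 4; ++i)
      for (int d = 0; d < 3; ++d) X(i, d) = nodes(elems(e, i) - 1, d);
    double vol;
    elem_geometry(X, gL, vol);
    bmatrix(L, gL, B);
    for (int n = 0; n < 10; ++n)
      for (int d = 0; d < 3; ++d)
        ue(3 * n + d) = u(3 * (elems(e, n) - 1) + d);
    eps = B * ue;
    C = cmatrix(Emod(e), nu(e));
    out.row(e) = (C * (eps - eig.row(e).t())).t();
  }
  return out;
}
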