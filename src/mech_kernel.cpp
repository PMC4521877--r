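// Co-rotational linear-elastic tetrahedra with fiber-aligned active stress,
// plus cavity volume / pressure-load evaluation. Inner loop of the
// mechanics module; everything else (time integration, valve phases,
// Windkessel coupling) lives in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 3x3 helpers on raw row-major arrays (avoid small-object overhead in the
// per-element hot loop).
static inline double det3(const double* A) {
  return A[0] * (A[4] * A[8] - A[5] * A[7]) -
         A[1] * (A[3] * A[8] - A[5] * A[6]) +
         A[2] * (A[3] * A[7] - A[4] * A[6]);
}

static inline bool invT3(const double* A, double* R) {
  // R = inv(A)^T (row-major)
  double d = det3(A);
  if (std::abs(d) < 1e-14) return false;
  double id = 1.0 / d;
  // cofactor matrix / det = inv(A)^T
  R[0] = (A[4] * A[8] - A[5] * A[7]) * id;
  R[1] = (A[5] * A[6] - A[3] * A[8]) * id;
  R[2] = (A[3] * A[7] - A[4] * A[6]) * id;
  R[3] = (A[2] * A[7] - A[1] * A[8]) * id;
  R[4] = (A[0] * A[8] - A[2] * A[6]) * id;
  R[5] = (A[1] * A[6] - A[0] * A[7]) * id;
  R[6] = (A[1] * A[5] - A[2] * A[4]) * id;
  R[7] = (A[2] * A[3] - A[0] * A[5]) * id;
  R[8] = (A[0] * A[4] - A[1] * A[3]) * id;
  return true;
}

// Rotation factor of the polar decomposition (scaled Higham iteration;
// globally convergent for nonsingular F, quadratic near the solution).
static void polar_rotation(const double* F, double* R) {
  double X[9], Xi[9];
  double d = det3(F);
  if (d <= 1e-12) {
    for (int i = 0; i < 9; ++i) R[i] = (i % 4 == 0);
    return;
  }
  // determinant scaling accelerates early iterations
  double s = std::pow(std::abs(d), -1.0 / 3.0);
  for (int i = 0; i < 9; ++i) X[i] = F[i] * s;
  for (int it = 0; it < 8; ++it) {
    if (!invT3(X, Xi)) break;
    double diff = 0;
    for (int i = 0; i < 9; ++i) {
      double xn = 0.5 * (X[i] + Xi[i]);
      diff += std::abs(xn - X[i]);
      X[i] = xn;
    }
    if (diff < 1e-9) break;
  }
  for (int i = 0; i < 9; ++i) R[i] = X[i];
}

// Per-element setup: shape gradients, volumes, isotropic stiffness.
// [[Rcpp::export]]
List mech_setup_cpp(const arma::mat& nodes, const arma::imat& tets,
                    double E, double nu, double density) {
  const int M = tets.n_rows;
  arma::mat grad(M, 12);
  arma::vec vol(M);
  arma::mat invDm(M, 9);
  arma::cube Ke(12, 12, M);
  arma::vec mass(nodes.n_rows, arma::fill::zeros);

  // isotropic elasticity matrix (Voigt)
  double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  double mu = E / (2 * (1 + nu));
  arma::mat66 Dm(arma::fill::zeros);
  Dm(0, 0) = Dm(1, 1) = Dm(2, 2) = lam + 2 * mu;
  Dm(0, 1) = Dm(0, 2) = Dm(1, 0) = Dm(1, 2) = Dm(2, 0) = Dm(2, 1) = lam;
  Dm(3, 3) = Dm(4, 4) = Dm(5, 5) = mu;

  for (int e = 0; e < M; ++e) {
    arma::mat33 Dmat;
    arma::vec3 p1 = nodes.row(tets(e, 0) - 1).t();
    for (int c = 0; c < 3; ++c) {
      Dmat.col(c) = nodes.row(tets(e, c + 1) - 1).t() - p1;
    }
    double det = arma::det(Dmat);
    if (det <= 0) stop("inverted reference element %d", e + 1);
    vol(e) = det / 6.0;
    arma::mat33 inv = arma::inv(Dmat);
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) invDm(e, 3 * r + c) = inv(r, c);
    // gradients: rows of inv are grads of nodes 2..4; node 1 = -sum
    arma::mat g(3, 4);
    g.col(1) = inv.row(0).t();
    g.col(2) = inv.row(1).t();
    g.col(3) = inv.row(2).t();
    g.col(0) = -(g.col(1) + g.col(2) + g.col(3));
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) grad(e, 3 * a + c) = g(c, a);
    // B matrix (6 x 12)
    arma::mat B(6, 12, arma::fill::zeros);
    for (int a = 0; a < 4; ++a) {
      double gx = g(0, a), gy = g(1, a), gz = g(2, a);
      B(0, 3 * a) = gx; B(1, 3 * a + 1) = gy; B(2, 3 * a + 2) = gz;
      B(3, 3 * a) = gy; B(3, 3 * a + 1) = gx;
      B(4, 3 * a + 1) = gz; B(4, 3 * a + 2) = gy;
      B(5, 3 * a) = gz; B(5, 3 * a + 2) = gx;
    }
    Ke.slice(e) = vol(e) * B.t() * Dm * B;
    for (int a = 0; a < 4; ++a) mass(tets(e, a) - 1) += density * vol(e) / 4.0;
  }
  return List::create(_["grad"] = grad, _["vol"] = vol,
                      _["invDm"] = invDm, _["Ke"] = Ke, _["mass"] = mass);
}

// Internal nodal forces (co-rotational passive + fiber active stress) and
// elastic energy. Forces are in stress units (kPa * mm^2); the caller owns
// the conversion to dynamical units. sigma_a: per-element active stress
// (kPa), fibers: per-element unit reference fiber directions.
// [[Rcpp::export]]
List mech_force_cpp(NumericMatrix nodes, IntegerMatrix tets,
                    NumericVector U, List setup,
                    NumericVector sigma_a, NumericMatrix fibers) {
  const int M = tets.nrow();
  NumericMatrix grad = setup["grad"];
  NumericVector vol = setup["vol"];
  NumericMatrix invDm = setup["invDm"];
  NumericVector KeV = setup["Ke"];  // 12 x 12 x M array, column-major slices
  NumericVector F(U.size());
  double energy = 0.0;
  int n_degenerate = 0;
  const double* Uptr = &U[0];
  double* Fptr = &F[0];

  for (int e = 0; e < M; ++e) {
    int id[4];
    double x0[12], x[12];  // column a at [3a..3a+2]
    for (int a = 0; a < 4; ++a) {
      int nd = tets(e, a) - 1;
      id[a] = nd;
      for (int c = 0; c < 3; ++c) {
        x0[3 * a + c] = nodes(nd, c);
        x[3 * a + c] = nodes(nd, c) + Uptr[3 * nd + c];
      }
    }
    // deformation gradient, row-major: F = Ds * invDm
    double Ds[9], Fd[9];
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) Ds[3 * r + c] = x[3 * (c + 1) + r] - x[r];
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += Ds[3 * r + k] * invDm(e, 3 * k + c);
        Fd[3 * r + c] = s;
      }
    if (det3(Fd) <= 0) ++n_degenerate;
    double R[9];
    polar_rotation(Fd, R);

    // d = R^T x - x0 per node
    double d[12];
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c)
        d[3 * a + c] = R[c] * x[3 * a] + R[3 + c] * x[3 * a + 1] +
                       R[6 + c] * x[3 * a + 2] - x0[3 * a + c];
    // fl = Ke d (Ke slice is column-major 12x12, symmetric)
    const double* K = &KeV[144 * e];
    double fl[12];
    for (int i = 0; i < 12; ++i) {
      double s = 0;
      const double* col = K + 12 * i;  // symmetric: column i == row i
      for (int j = 0; j < 12; ++j) s += col[j] * d[j];
      fl[i] = s;
      energy += 0.5 * s * d[i];
    }
    // rotate back and scatter
    for (int a = 0; a < 4; ++a) {
      double fx = fl[3 * a], fy = fl[3 * a + 1], fz = fl[3 * a + 2];
      double* Fo = Fptr + 3 * id[a];
      Fo[0] += R[0] * fx + R[1] * fy + R[2] * fz;
      Fo[1] += R[3] * fx + R[4] * fy + R[5] * fz;
      Fo[2] += R[6] * fx + R[7] * fy + R[8] * fz;
    }
    double sa = sigma_a(e);
    if (sa != 0.0) {
      double f0[3] = {fibers(e, 0), fibers(e, 1), fibers(e, 2)};
      double rf[3] = {R[0] * f0[0] + R[1] * f0[1] + R[2] * f0[2],
                      R[3] * f0[0] + R[4] * f0[1] + R[5] * f0[2],
                      R[6] * f0[0] + R[7] * f0[1] + R[8] * f0[2]};
      for (int a = 0; a < 4; ++a) {
        double gdotf = grad(e, 3 * a) * f0[0] + grad(e, 3 * a + 1) * f0[1] +
                       grad(e, 3 * a + 2) * f0[2];
        double s = sa * vol(e) * gdotf;
        double* Fo = Fptr + 3 * id[a];
        Fo[0] += s * rf[0]; Fo[1] += s * rf[1]; Fo[2] += s * rf[2];
      }
    }
  }
  return List::create(_["force"] = F, _["energy"] = energy,
                      _["n_degenerate"] = n_degenerate);
}

// Cavity volume (divergence theorem with fan cap over the base ring) and,
// optionally, the nodal load vector for unit cavity pressure (kPa).
// `facets` are oriented outward from the tissue (into the cavity);
// `cap_edges` are the oriented boundary edges of the flipped surface;
// `ring_nodes` the unique base-ring node indices.
// [[Rcpp::export]]
List cavity_cpp(NumericMatrix nodes, NumericVector U,
                IntegerMatrix facets, IntegerMatrix cap_edges,
                IntegerVector ring_nodes, bool want_load) {
  auto pos = [&](int nd, int c) { return nodes(nd, c) + U[3 * nd + c]; };
  double vol6 = 0.0;
  NumericVector b(want_load ? U.size() : 1);

  for (int f = 0; f < facets.nrow(); ++f) {
    int i = facets(f, 0) - 1, j = facets(f, 1) - 1, k = facets(f, 2) - 1;
    arma::vec3 a, bb, cc;
    for (int c = 0; c < 3; ++c) {
      a(c) = pos(i, c); bb(c) = pos(j, c); cc(c) = pos(k, c);
    }
    // flipped orientation (a, c, b): outward from the blood pool
    arma::vec3 crossv = arma::cross(cc - a, bb - a);
    vol6 += arma::dot(a, crossv);
    if (want_load) {
      // area vector of the facet as stored (points into the cavity);
      // pressure pushes the wall away from the cavity: -p * A / 3 per node
      arma::vec3 A = 0.5 * arma::cross(bb - a, cc - a);
      for (int c = 0; c < 3; ++c) {
        double fc = -A(c) / 3.0;
        b(3 * i + c) += fc; b(3 * j + c) += fc; b(3 * k + c) += fc;
      }
    }
  }
  if (cap_edges.nrow() > 0) {
    arma::vec3 cen(arma::fill::zeros);
    for (int r = 0; r < ring_nodes.size(); ++r) {
      int nd = ring_nodes[r] - 1;
      for (int c = 0; c < 3; ++c) cen(c) += pos(nd, c);
    }
    cen /= (double)ring_nodes.size();
    for (int e = 0; e < cap_edges.nrow(); ++e) {
      int i = cap_edges(e, 0) - 1, j = cap_edges(e, 1) - 1;
      arma::vec3 a, bb;
      for (int c = 0; c < 3; ++c) { a(c) = pos(i, c); bb(c) = pos(j, c); }
      // triangle (cen, b, a)
      vol6 += arma::dot(cen, arma::cross(bb, a));
    }
  }
  double V = vol6 / 6.0 / 1000.0;  // ml
  if (want_load) {
    return List::create(_["volume"] = V, _["load"] = b);
  }
  return List::create(_["volume"] = V);
}
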