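// Low-level kernels for tensor volume math and registration.
//
// Tensor component order everywhere: (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)
// (NIfTI lower-triangular). Voxel coordinates are 0-based doubles.
// All dense fields are passed as n x k matrices in R's column-major
// voxel order (index = i + nx*(j + ny*k)).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline void unpack6(const double* c, arma::mat33& M) {
  M(0,0) = c[0]; M(0,1) = M(1,0) = c[1]; M(1,1) = c[2];
  M(0,2) = M(2,0) = c[3]; M(1,2) = M(2,1) = c[4]; M(2,2) = c[5];
}

static inline void pack6_row(const arma::mat33& M, NumericMatrix& out, int r) {
  out(r,0) = M(0,0); out(r,1) = M(0,1); out(r,2) = M(1,1);
  out(r,3) = M(0,2); out(r,4) = M(1,2); out(r,5) = M(2,2);
}

// [[Rcpp::export]]
List cpp_eig3_batch(const NumericMatrix& D6) {
  const int n = D6.nrow();
  NumericMatrix vals(n, 3);   // descending
  NumericMatrix vecs(n, 9);   // columns of V for eigenvalues in descending order
  arma::mat33 M, V;
  arma::vec3 ev;
  for (int r = 0; r < n; ++r) {
    double c[6];
    for (int k = 0; k < 6; ++k) c[k] = D6(r, k);
    unpack6(c, M);
    arma::eig_sym(ev, V, M);          // ascending
    for (int k = 0; k < 3; ++k) {
      vals(r, k) = ev(2 - k);
      for (int d = 0; d < 3; ++d) vecs(r, 3 * k + d) = V(d, 2 - k);
    }
  }
  return List::create(_["values"] = vals, _["vectors"] = vecs);
}

// matrix log with eigenvalue clamping at lam_floor
// [[Rcpp::export]]
NumericMatrix cpp_tensor_log(const NumericMatrix& D6, double lam_floor) {
  const int n = D6.nrow();
  NumericMatrix out(n, 6);
  arma::mat33 M, V, L;
  arma::vec3 ev;
  for (int r = 0; r < n; ++r) {
    double c[6];
    for (int k = 0; k < 6; ++k) c[k] = D6(r, k);
    unpack6(c, M);
    arma::eig_sym(ev, V, M);
    for (int k = 0; k < 3; ++k) ev(k) = std::log(std::max(ev(k), lam_floor));
    L = V * arma::diagmat(ev) * V.t();
    pack6_row(L, out, r);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_tensor_exp(const NumericMatrix& L6) {
  const int n = L6.nrow();
  NumericMatrix out(n, 6);
  arma::mat33 M, V, E;
  arma::vec3 ev;
  for (int r = 0; r < n; ++r) {
    double c[6];
    for (int k = 0; k < 6; ++k) c[k] = L6(r, k);
    unpack6(c, M);
    arma::eig_sym(ev, V, M);
    for (int k = 0; k < 3; ++k) ev(k) = std::exp(ev(k));
    E = V * arma::diagmat(ev) * V.t();
    pack6_row(E, out, r);
  }
  return out;
}

// FA from clamped eigenvalues, MD from the raw trace.
// [[Rcpp::export]]
List cpp_fa_md(const NumericMatrix& D6, double lam_floor) {
  const int n = D6.nrow();
  NumericVector fa(n), md(n);
  arma::mat33 M, V;
  arma::vec3 ev;
  for (int r = 0; r < n; ++r) {
    double c[6];
    for (int k = 0; k < 6; ++k) c[k] = D6(r, k);
    md[r] = (c[0] + c[2] + c[5]) / 3.0;
    unpack6(c, M);
    arma::eig_sym(ev, V, M);
    double l1 = std::max(ev(0), lam_floor), l2 = std::max(ev(1), lam_floor),
           l3 = std::max(ev(2), lam_floor);
    double m = (l1 + l2 + l3) / 3.0;
    double num = (l1 - m) * (l1 - m) + (l2 - m) * (l2 - m) + (l3 - m) * (l3 - m);
    double den = l1 * l1 + l2 * l2 + l3 * l3;
    fa[r] = (den > 0.0) ? std::sqrt(1.5 * num / den) : 0.0;
    if (fa[r] > 1.0) fa[r] = 1.0;
  }
  return List::create(_["fa"] = fa, _["md"] = md);
}

// principal eigenvector with deterministic sign (first component with
// magnitude > 1e-12 made positive); flags near-degenerate leading pairs
// [[Rcpp::export]]
List cpp_principal_eigvec(const NumericMatrix& D6) {
  const int n = D6.nrow();
  NumericMatrix vec(n, 3);
  LogicalVector degen(n);
  arma::mat33 M, V;
  arma::vec3 ev;
  for (int r = 0; r < n; ++r) {
    double c[6];
    for (int k = 0; k < 6; ++k) c[k] = D6(r, k);
    unpack6(c, M);
    arma::eig_sym(ev, V, M);
    double l1 = ev(2), l2 = ev(1);
    degen[r] = (l1 - l2) < 1e-12 * std::abs(l1);
    double v0 = V(0, 2), v1 = V(1, 2), v2 = V(2, 2);
    double s = 1.0;
    if (std::abs(v0) > 1e-12)      s = (v0 > 0) ? 1.0 : -1.0;
    else if (std::abs(v1) > 1e-12) s = (v1 > 0) ? 1.0 : -1.0;
    else if (std::abs(v2) > 1e-12) s = (v2 > 0) ? 1.0 : -1.0;
    vec(r, 0) = s * v0; vec(r, 1) = s * v1; vec(r, 2) = s * v2;
  }
  return List::create(_["vectors"] = vec, _["degenerate"] = degen);
}

struct Tri {
  int i0, j0, k0;
  double w[8]; // order: (i0,j0,k0),(i1,j0,k0),(i0,j1,k0),(i1,j1,k0), then k1 plane
};

static inline bool tri_setup(double x, double y, double z, const int* d,
                             bool clamp, Tri& t) {
  if (clamp) {
    x = std::min(std::max(x, 0.0), (double)(d[0] - 1));
    y = std::min(std::max(y, 0.0), (double)(d[1] - 1));
    z = std::min(std::max(z, 0.0), (double)(d[2] - 1));
  } else if (x < 0 || y < 0 || z < 0 ||
             x > d[0] - 1 || y > d[1] - 1 || z > d[2] - 1) {
    return false;
  }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > d[0] - 2) i0 = std::max(d[0] - 2, 0);
  if (j0 > d[1] - 2) j0 = std::max(d[1] - 2, 0);
  if (k0 > d[2] - 2) k0 = std::max(d[2] - 2, 0);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  t.i0 = i0; t.j0 = j0; t.k0 = k0;
  double gx = 1 - fx, gy = 1 - fy, gz = 1 - fz;
  t.w[0] = gx * gy * gz; t.w[1] = fx * gy * gz;
  t.w[2] = gx * fy * gz; t.w[3] = fx * fy * gz;
  t.w[4] = gx * gy * fz; t.w[5] = fx * gy * fz;
  t.w[6] = gx * fy * fz; t.w[7] = fx * fy * fz;
  return true;
}

static inline double tri_gather(const double* col, const int* d, const Tri& t) {
  const int nx = d[0], nxy = d[0] * d[1];
  int ix1 = (d[0] > 1) ? 1 : 0, jy1 = (d[1] > 1) ? nx : 0, kz1 = (d[2] > 1) ? nxy : 0;
  const double* p = col + t.i0 + nx * t.j0 + nxy * t.k0;
  return t.w[0] * p[0] + t.w[1] * p[ix1] + t.w[2] * p[jy1] + t.w[3] * p[ix1 + jy1]
       + t.w[4] * p[kz1] + t.w[5] * p[ix1 + kz1] + t.w[6] * p[jy1 + kz1]
       + t.w[7] * p[ix1 + jy1 + kz1];
}

// generic multi-channel trilinear resampler; map holds 0-based source voxel
// coordinates per output sample. Out-of-field samples get `oob` per channel.
// [[Rcpp::export]]
NumericMatrix cpp_resample_channels(const NumericMatrix& src, const IntegerVector& dim,
                                    const NumericMatrix& map, NumericVector oob,
                                    bool clamp) {
  const int n = map.nrow(), nc = src.ncol();
  int d[3] = { dim[0], dim[1], dim[2] };
  NumericMatrix out(n, nc);
  Tri t;
  for (int r = 0; r < n; ++r) {
    if (tri_setup(map(r, 0), map(r, 1), map(r, 2), d, clamp, t)) {
      for (int c = 0; c < nc; ++c)
        out(r, c) = tri_gather(&src(0, c), d, t);
    } else {
      for (int c = 0; c < nc; ++c) out(r, c) = oob[c % oob.size()];
    }
  }
  return out;
}

// tensor resampling: interpolate (optionally log-space) then reorient by a
// per-voxel or constant rotation: D' = R D R^t. rot has 1 or n rows of 9
// (column-major 3x3). Out-of-field -> isotropic floor tensor.
// [[Rcpp::export]]
NumericMatrix cpp_resample_tensor(const NumericMatrix& src6, const IntegerVector& dim,
                                  const NumericMatrix& map, const NumericMatrix& rot,
                                  bool log_space, double lam_floor) {
  const int n = map.nrow();
  int d[3] = { dim[0], dim[1], dim[2] };
  NumericMatrix out(n, 6);
  const bool per_voxel = rot.nrow() == n;
  arma::mat33 M, V, R, T;
  arma::vec3 ev;
  const double floor_val = log_space ? std::log(lam_floor) : lam_floor;
  Tri t;
  for (int r = 0; r < n; ++r) {
    double c[6];
    if (tri_setup(map(r, 0), map(r, 1), map(r, 2), d, false, t)) {
      for (int k = 0; k < 6; ++k) c[k] = tri_gather(&src6(0, k), d, t);
    } else {
      c[0] = c[2] = c[5] = floor_val; c[1] = c[3] = c[4] = 0.0;
    }
    unpack6(c, M);
    if (log_space) {
      arma::eig_sym(ev, V, M);
      for (int k = 0; k < 3; ++k) ev(k) = std::exp(ev(k));
      M = V * arma::diagmat(ev) * V.t();
    }
    const int rr = per_voxel ? r : 0;
    R(0,0)=rot(rr,0); R(1,0)=rot(rr,1); R(2,0)=rot(rr,2);
    R(0,1)=rot(rr,3); R(1,1)=rot(rr,4); R(2,1)=rot(rr,5);
    R(0,2)=rot(rr,6); R(1,2)=rot(rr,7); R(2,2)=rot(rr,8);
    T = R * M * R.t();
    pack6_row(T, out, r);
  }
  return out;
}

// Registration cost: mean squared Frobenius difference between fixed tensors
// (rows of fix6 at voxel coords `coords` on the fixed grid) and the moving
// tensor field sampled through the voxel-to-voxel affine V (4x4), reoriented
// by the constant rotation R (3x3). Out-of-field samples are treated as the
// isotropic floor tensor. Returns c(cost, in-field fraction).
// [[Rcpp::export]]
NumericVector cpp_cost_tensor(const NumericMatrix& mov6, const IntegerVector& mdim,
                              const NumericMatrix& fix6, const NumericMatrix& coords,
                              const NumericMatrix& V, const NumericMatrix& R,
                              double lam_floor, double cap = R_PosInf) {
  const int m = coords.nrow();
  int d[3] = { mdim[0], mdim[1], mdim[2] };
  const double v00=V(0,0), v01=V(0,1), v02=V(0,2), v03=V(0,3);
  const double v10=V(1,0), v11=V(1,1), v12=V(1,2), v13=V(1,3);
  const double v20=V(2,0), v21=V(2,1), v22=V(2,2), v23=V(2,3);
  const double r00=R(0,0), r01=R(0,1), r02=R(0,2);
  const double r10=R(1,0), r11=R(1,1), r12=R(1,2);
  const double r20=R(2,0), r21=R(2,1), r22=R(2,2);
  double acc = 0.0; int infield = 0;
  Tri t;
  for (int r = 0; r < m; ++r) {
    const double x = coords(r,0), y = coords(r,1), z = coords(r,2);
    const double sx = v00*x + v01*y + v02*z + v03;
    const double sy = v10*x + v11*y + v12*z + v13;
    const double sz = v20*x + v21*y + v22*z + v23;
    double c[6];
    if (tri_setup(sx, sy, sz, d, false, t)) {
      for (int k = 0; k < 6; ++k) c[k] = tri_gather(&mov6(0, k), d, t);
      ++infield;
    } else {
      c[0] = c[2] = c[5] = lam_floor; c[1] = c[3] = c[4] = 0.0;
    }
    // A = R * D
    const double a00 = r00*c[0] + r01*c[1] + r02*c[3];
    const double a01 = r00*c[1] + r01*c[2] + r02*c[4];
    const double a02 = r00*c[3] + r01*c[4] + r02*c[5];
    const double a10 = r10*c[0] + r11*c[1] + r12*c[3];
    const double a11 = r10*c[1] + r11*c[2] + r12*c[4];
    const double a12 = r10*c[3] + r11*c[4] + r12*c[5];
    const double a20 = r20*c[0] + r21*c[1] + r22*c[3];
    const double a21 = r20*c[1] + r21*c[2] + r22*c[4];
    const double a22 = r20*c[3] + r21*c[4] + r22*c[5];
    // D' = A * R^t  (symmetric; need 6 entries)
    const double dxx = a00*r00 + a01*r01 + a02*r02 - fix6(r,0);
    const double dxy = a00*r10 + a01*r11 + a02*r12 - fix6(r,1);
    const double dyy = a10*r10 + a11*r11 + a12*r12 - fix6(r,2);
    const double dxz = a00*r20 + a01*r21 + a02*r22 - fix6(r,3);
    const double dyz = a10*r20 + a11*r21 + a12*r22 - fix6(r,4);
    const double dzz = a20*r20 + a21*r21 + a22*r22 - fix6(r,5);
    const double d2 = dxx*dxx + dyy*dyy + dzz*dzz
      + 2.0*(dxy*dxy + dxz*dxz + dyz*dyz);
    acc += (d2 < cap) ? d2 : cap;   // robust capped quadratic
  }
  return NumericVector::create(acc / m, (double)infield / m);
}

// Scalar-mode analogue on (FA) images; out-of-field sampled as 0.
// [[Rcpp::export]]
NumericVector cpp_cost_scalar(const NumericVector& mov, const IntegerVector& mdim,
                              const NumericVector& fixv, const NumericMatrix& coords,
                              const NumericMatrix& V) {
  const int m = coords.nrow();
  int d[3] = { mdim[0], mdim[1], mdim[2] };
  const double v00=V(0,0), v01=V(0,1), v02=V(0,2), v03=V(0,3);
  const double v10=V(1,0), v11=V(1,1), v12=V(1,2), v13=V(1,3);
  const double v20=V(2,0), v21=V(2,1), v22=V(2,2), v23=V(2,3);
  double acc = 0.0; int infield = 0;
  Tri t;
  const double* src = &mov[0];
  for (int r = 0; r < m; ++r) {
    const double x = coords(r,0), y = coords(r,1), z = coords(r,2);
    double val = 0.0;
    if (tri_setup(v00*x + v01*y + v02*z + v03,
                  v10*x + v11*y + v12*z + v13,
                  v20*x + v21*y + v22*z + v23, d, false, t)) {
      val = tri_gather(src, d, t);
      ++infield;
    }
    const double diff = val - fixv[r];
    acc += diff * diff;
  }
  return NumericVector::create(acc / m, (double)infield / m);
}

// Finite-strain reorientation rotations from pull-back Jacobians.
// Input: n x 9 world-frame Jacobians J (column-major 3x3) of the resampling
// map; output: n x 9 rotations R = polar_rot(J)^t (the rotation factor of
// the forward map). Newton iteration X <- (X + X^-t)/2. Non-invertible J
// (|det| < 1e-12) flagged and given the identity.
// [[Rcpp::export]]
List cpp_reorient_rotations(const NumericMatrix& J) {
  const int n = J.nrow();
  NumericMatrix out(n, 9);
  LogicalVector bad(n);
  arma::mat33 X, Xi;
  for (int r = 0; r < n; ++r) {
    X(0,0)=J(r,0); X(1,0)=J(r,1); X(2,0)=J(r,2);
    X(0,1)=J(r,3); X(1,1)=J(r,4); X(2,1)=J(r,5);
    X(0,2)=J(r,6); X(1,2)=J(r,7); X(2,2)=J(r,8);
    if (std::abs(arma::det(X)) < 1e-12) {
      bad[r] = true;
      X.eye();
    } else {
      if (arma::det(X) < 0) bad[r] = true;
      for (int it = 0; it < 30; ++it) {
        Xi = arma::inv(X).t();
        arma::mat33 Xn = 0.5 * (X + Xi);
        double delta = arma::abs(Xn - X).max();
        X = Xn;
        if (delta < 1e-12) break;
      }
      X = X.t(); // rotation of the forward map
    }
    out(r,0)=X(0,0); out(r,1)=X(1,0); out(r,2)=X(2,0);
    out(r,3)=X(0,1); out(r,4)=X(1,1); out(r,5)=X(2,1);
    out(r,6)=X(0,2); out(r,7)=X(1,2); out(r,8)=X(2,2);
  }
  return List::create(_["rot"] = out, _["bad"] = bad);
}

// Jacobian determinant of x -> x + u(x) for a displacement field in world mm
// on a grid with world-to-voxel linear map given by invLin = inv(A[1:3,1:3]).
// Central differences inside, one-sided at boundaries.
// [[Rcpp::export]]
NumericVector cpp_jacdet(const NumericMatrix& U, const IntegerVector& dim,
                         const NumericMatrix& invLin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  arma::mat33 G, Li, Jm;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) Li(a, b) = invLin(a, b);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int idx = i + nx * (j + ny * k);
        // dU/dvoxel
        for (int c = 0; c < 3; ++c) {
          int ip = std::min(i + 1, nx - 1), im = std::max(i - 1, 0);
          int jp = std::min(j + 1, ny - 1), jm = std::max(j - 1, 0);
          int kp = std::min(k + 1, nz - 1), km = std::max(k - 1, 0);
          G(c, 0) = (U(ip + nx * (j + ny * k), c) - U(im + nx * (j + ny * k), c)) / (ip - im);
          G(c, 1) = (U(i + nx * (jp + ny * k), c) - U(i + nx * (jm + ny * k), c)) / (jp - jm);
          G(c, 2) = (U(i + nx * (j + ny * kp), c) - U(i + nx * (j + ny * km), c)) / (kp - km);
        }
        Jm = G * Li;
        Jm(0,0) += 1.0; Jm(1,1) += 1.0; Jm(2,2) += 1.0;
        out[idx] = arma::det(Jm);
      }
  return out;
}

// factor-2 block-mean downsampling of a multi-channel field
// [[Rcpp::export]]
List cpp_downsample2(const NumericMatrix& src, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], nc = src.ncol();
  const int ox = (nx + 1) / 2, oy = (ny + 1) / 2, oz = (nz + 1) / 2;
  NumericMatrix out(ox * oy * oz, nc);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        const int oidx = i + ox * (j + oy * k);
        int cnt = 0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const int si = 2 * i + di, sj = 2 * j + dj, sk = 2 * k + dk;
              if (si < nx && sj < ny && sk < nz) {
                const int sidx = si + nx * (sj + ny * sk);
                for (int c = 0; c < nc; ++c) out(oidx, c) += src(sidx, c);
                ++cnt;
              }
            }
        for (int c = 0; c < nc; ++c) out(oidx, c) /= cnt;
      }
  return List::create(_["values"] = out,
                      _["dim"] = IntegerVector::create(ox, oy, oz));
}

static inline void polar_rot_newton(const arma::mat33& L, arma::mat33& R) {
  // rotation factor of L by Newton iteration; caller ensures det(L) > 0
  arma::mat33 X = L, Xi;
  for (int it = 0; it < 20; ++it) {
    Xi = arma::inv(X).t();
    arma::mat33 Xn = 0.5 * (X + Xi);
    if (arma::abs(Xn - X).max() < 1e-12) { X = Xn; break; }
    X = Xn;
  }
  R = X;
}

static double block_cost(const NumericMatrix& mov, const int* d, bool scalar,
                         const NumericMatrix& bfix, const NumericMatrix& coords,
                         const arma::mat44& V, const arma::mat33& R,
                         double oob_diag, double cap) {
  const int m = coords.nrow();
  double acc = 0.0;
  Tri t;
  for (int r = 0; r < m; ++r) {
    const double x = coords(r,0), y = coords(r,1), z = coords(r,2);
    const double sx = V(0,0)*x + V(0,1)*y + V(0,2)*z + V(0,3);
    const double sy = V(1,0)*x + V(1,1)*y + V(1,2)*z + V(1,3);
    const double sz = V(2,0)*x + V(2,1)*y + V(2,2)*z + V(2,3);
    if (scalar) {
      double val = 0.0;
      if (tri_setup(sx, sy, sz, d, false, t)) val = tri_gather(&mov(0,0), d, t);
      const double diff = val - bfix(r, 0);
      acc += diff * diff;
      continue;
    }
    double c[6];
    if (tri_setup(sx, sy, sz, d, false, t)) {
      for (int k = 0; k < 6; ++k) c[k] = tri_gather(&mov(0, k), d, t);
    } else {
      c[0] = c[2] = c[5] = oob_diag; c[1] = c[3] = c[4] = 0.0;
    }
    const double a00 = R(0,0)*c[0] + R(0,1)*c[1] + R(0,2)*c[3];
    const double a01 = R(0,0)*c[1] + R(0,1)*c[2] + R(0,2)*c[4];
    const double a02 = R(0,0)*c[3] + R(0,1)*c[4] + R(0,2)*c[5];
    const double a10 = R(1,0)*c[0] + R(1,1)*c[1] + R(1,2)*c[3];
    const double a11 = R(1,0)*c[1] + R(1,1)*c[2] + R(1,2)*c[4];
    const double a12 = R(1,0)*c[3] + R(1,1)*c[4] + R(1,2)*c[5];
    const double a20 = R(2,0)*c[0] + R(2,1)*c[1] + R(2,2)*c[3];
    const double a21 = R(2,0)*c[1] + R(2,1)*c[2] + R(2,2)*c[4];
    const double a22 = R(2,0)*c[3] + R(2,1)*c[4] + R(2,2)*c[5];
    const double dxx = a00*R(0,0) + a01*R(0,1) + a02*R(0,2) - bfix(r,0);
    const double dxy = a00*R(1,0) + a01*R(1,1) + a02*R(1,2) - bfix(r,1);
    const double dyy = a10*R(1,0) + a11*R(1,1) + a12*R(1,2) - bfix(r,2);
    const double dxz = a00*R(2,0) + a01*R(2,1) + a02*R(2,2) - bfix(r,3);
    const double dyz = a10*R(2,0) + a11*R(2,1) + a12*R(2,2) - bfix(r,4);
    const double dzz = a20*R(2,0) + a21*R(2,1) + a22*R(2,2) - bfix(r,5);
    const double d2 = dxx*dxx + dyy*dyy + dzz*dzz
      + 2.0*(dxy*dxy + dxz*dxz + dyz*dyz);
    acc += (d2 < cap) ? d2 : cap;
  }
  return acc / m;
}

// Fit one local affine block increment by pattern search (fully in C++).
// Parameters q[0..2] translation (mm), q[3..11] linear deviation
// (column-major). B(x) = cb + (I+Ldev)(x - cb) + t; cost is the (scalar or
// log-tensor Frobenius) block cost plus pen_w * mean squared corner
// displacement. Returns list(par, value).
// [[Rcpp::export]]
List cpp_fit_block(const NumericMatrix& mov, const IntegerVector& dim,
                   bool scalar, const NumericMatrix& bfix,
                   const NumericMatrix& coords, const NumericMatrix& aff,
                   const NumericMatrix& cb_, const NumericMatrix& corners,
                   const NumericVector& steps0, const NumericVector& mins,
                   int max_sweeps, double pen_w, double oob_diag, double cap) {
  int d[3] = { dim[0], dim[1], dim[2] };
  arma::mat44 A, Ainv;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) A(a, b) = aff(a, b);
  Ainv = arma::inv(A);
  arma::vec3 cb;
  for (int a = 0; a < 3; ++a) cb(a) = cb_(0, a);

  std::vector<double> q(12, 0.0), steps(12);
  for (int i = 0; i < 12; ++i) steps[i] = steps0[i];

  auto eval = [&](const std::vector<double>& p) -> double {
    arma::mat33 L;
    L(0,0)=1+p[3]; L(1,0)=p[4]; L(2,0)=p[5];
    L(0,1)=p[6]; L(1,1)=1+p[7]; L(2,1)=p[8];
    L(0,2)=p[9]; L(1,2)=p[10]; L(2,2)=1+p[11];
    if (arma::det(L) < 0.05) return R_PosInf;
    arma::mat44 B(arma::fill::eye);
    B.submat(0,0,2,2) = L;
    arma::vec3 t = { p[0], p[1], p[2] };
    B.submat(0,3,2,3) = cb + t - L * cb;
    arma::mat44 V = Ainv * B * A;
    arma::mat33 R;
    if (scalar) R.eye();
    else { arma::mat33 Li = arma::inv(L); polar_rot_newton(Li, R); R = R.t(); }
    double pen = 0.0;
    for (int cr = 0; cr < corners.nrow(); ++cr) {
      arma::vec3 cw = { corners(cr,0), corners(cr,1), corners(cr,2) };
      arma::vec3 disp = L * (cw - cb) + cb + t - cw;
      pen += arma::dot(disp, disp);
    }
    pen /= corners.nrow();
    // inline cost (avoid R matrices): reuse block_cost with arma views
    arma::mat33 Rm = R;
    return block_cost(mov, d, scalar, bfix, coords, V, Rm, oob_diag, cap) +
      pen_w * pen;
  };

  double f0 = eval(q);
  int sweeps = 0;
  for (;;) {
    bool improved = false;
    for (int i = 0; i < 12; ++i) {
      for (int s = 1; s >= -1; s -= 2) {
        std::vector<double> cand = q;
        cand[i] += s * steps[i];
        double fc = eval(cand);
        if (fc < f0 - std::abs(f0) * 1e-12) {
          q = cand; f0 = fc; improved = true; break;
        }
      }
    }
    ++sweeps;
    if (!improved) {
      bool done = true;
      for (int i = 0; i < 12; ++i) if (steps[i] > mins[i] * (1 + 1e-12)) done = false;
      if (done) break;
      for (int i = 0; i < 12; ++i) steps[i] = std::max(steps[i] * 0.5, (double)mins[i]);
    }
    if (sweeps >= max_sweeps) break;
  }
  return List::create(_["par"] = NumericVector(q.begin(), q.end()),
                      _["value"] = f0);
}
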