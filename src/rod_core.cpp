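// Corotational two-node beam element core for slender elastic rods.
//
// State: nodal positions (3 x n) and nodal rotation triads (3 x 3 x n,
// initialized to identity).  Each element carries its own initial frame E0
// (column 1 = initial tangent), so an initially curved rod meshed with
// straight chords is stress free in the reference configuration.
//
// Local elastic model per element: linear Euler-Bernoulli bending about both
// section axes (4-2-2-4 end-rotation stiffness), Saint-Venant torsion, and
// engineering axial stretch, all measured in a corotated frame that follows
// the chord and the mean nodal rotation.  Large rotations are handled by the
// frame extraction; local rotations stay small for reasonable meshes.
//
// The tangent is the exact Jacobian of the discrete internal force, obtained
// by central finite differences element-by-element (12 DOF each), so Newton
// converges quadratically on the discrete equations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat33 skew3(const vec3& v) {
  mat33 S;
  S(0, 0) = 0.0;   S(0, 1) = -v(2); S(0, 2) = v(1);
  S(1, 0) = v(2);  S(1, 1) = 0.0;   S(1, 2) = -v(0);
  S(2, 0) = -v(1); S(2, 1) = v(0);  S(2, 2) = 0.0;
  return S;
}

// Rodrigues formula, robust near zero.
static mat33 exp_so3(const vec3& w) {
  double th = norm(w);
  mat33 I = eye(3, 3);
  if (th < 1e-12) {
    return I + skew3(w) + 0.5 * skew3(w) * skew3(w);
  }
  mat33 K = skew3(w / th);
  return I + std::sin(th) * K + (1.0 - std::cos(th)) * (K * K);
}

// Rotation vector of a rotation matrix (angles expected well below pi).
static vec3 log_so3(const mat33& S) {
  vec3 w;
  w(0) = 0.5 * (S(2, 1) - S(1, 2));
  w(1) = 0.5 * (S(0, 2) - S(2, 0));
  w(2) = 0.5 * (S(1, 0) - S(0, 1));
  double s = norm(w);                    // = sin(theta)
  double c = 0.5 * (trace(S) - 1.0);     // = cos(theta)
  double th = std::atan2(s, c);
  if (s < 1e-12) return w;               // theta ~ 0 (or numerically tiny)
  return (th / s) * w;
}

static vec4 quat_from_R(const mat33& R) {
  vec4 q;
  double tr = trace(R);
  if (tr > 0.0) {
    double s = std::sqrt(tr + 1.0) * 2.0;
    q(0) = 0.25 * s;
    q(1) = (R(2, 1) - R(1, 2)) / s;
    q(2) = (R(0, 2) - R(2, 0)) / s;
    q(3) = (R(1, 0) - R(0, 1)) / s;
  } else if (R(0, 0) > R(1, 1) && R(0, 0) > R(2, 2)) {
    double s = std::sqrt(1.0 + R(0, 0) - R(1, 1) - R(2, 2)) * 2.0;
    q(0) = (R(2, 1) - R(1, 2)) / s;
    q(1) = 0.25 * s;
    q(2) = (R(0, 1) + R(1, 0)) / s;
    q(3) = (R(0, 2) + R(2, 0)) / s;
  } else if (R(1, 1) > R(2, 2)) {
    double s = std::sqrt(1.0 + R(1, 1) - R(0, 0) - R(2, 2)) * 2.0;
    q(0) = (R(0, 2) - R(2, 0)) / s;
    q(1) = (R(0, 1) + R(1, 0)) / s;
    q(2) = 0.25 * s;
    q(3) = (R(1, 2) + R(2, 1)) / s;
  } else {
    double s = std::sqrt(1.0 + R(2, 2) - R(0, 0) - R(1, 1)) * 2.0;
    q(0) = (R(1, 0) - R(0, 1)) / s;
    q(1) = (R(0, 2) + R(2, 0)) / s;
    q(2) = (R(1, 2) + R(2, 1)) / s;
    q(3) = 0.25 * s;
  }
  return q;
}

static mat33 R_from_quat(const vec4& qin) {
  vec4 q = normalise(qin);
  double w = q(0), x = q(1), y = q(2), z = q(3);
  mat33 R;
  R(0, 0) = 1 - 2 * (y * y + z * z);
  R(0, 1) = 2 * (x * y - z * w);
  R(0, 2) = 2 * (x * z + y * w);
  R(1, 0) = 2 * (x * y + z * w);
  R(1, 1) = 1 - 2 * (x * x + z * z);
  R(1, 2) = 2 * (y * z - x * w);
  R(2, 0) = 2 * (x * z - y * w);
  R(2, 1) = 2 * (y * z + x * w);
  R(2, 2) = 1 - 2 * (x * x + y * y);
  return R;
}

struct LocalState {
  double l;
  double u;       // axial stretch l - L0
  vec3 th1, th2;  // local nodal rotations in the corotated frame
  mat33 Re;       // corotated element frame (columns e1, e2, e3)
};

static LocalState element_local_state(const vec3& x1, const vec3& x2,
                                      const mat33& R1, const mat33& R2,
                                      const mat33& E0, double L0) {
  LocalState st;
  vec3 d = x2 - x1;
  st.l = norm(d);
  if (st.l <= 0.0) Rcpp::stop("degenerate element: coincident nodes");
  vec3 e1 = d / st.l;

  vec4 q1 = quat_from_R(R1);
  vec4 q2 = quat_from_R(R2);
  if (dot(q1, q2) < 0.0) q2 = -q2;
  mat33 Rm = R_from_quat(q1 + q2);  // mean nodal rotation

  vec3 r2 = Rm * E0.col(1);
  vec3 e3 = cross(e1, r2);
  double n3 = norm(e3);
  if (n3 < 1e-14) Rcpp::stop("degenerate element frame (tangent parallel to director)");
  e3 /= n3;
  vec3 e2 = cross(e3, e1);

  st.Re.col(0) = e1;
  st.Re.col(1) = e2;
  st.Re.col(2) = e3;
  st.u = st.l - L0;
  st.th1 = log_so3(st.Re.t() * (R1 * E0));
  st.th2 = log_so3(st.Re.t() * (R2 * E0));
  return st;
}

// Internal force of one element: 12-vector (f1, m1, f2, m2) in global axes.
static vec element_force(const vec3& x1, const vec3& x2,
                         const mat33& R1, const mat33& R2,
                         const mat33& E0, double L0,
                         double EA, double EI, double GJ) {
  LocalState st = element_local_state(x1, x2, R1, R2, E0, L0);
  const vec3 e1 = st.Re.col(0), e2 = st.Re.col(1), e3 = st.Re.col(2);

  double N   = EA * st.u / L0;
  double Mt  = GJ * (st.th2(0) - st.th1(0)) / L0;
  double M12 = EI / L0 * (4.0 * st.th1(1) + 2.0 * st.th2(1));
  double M22 = EI / L0 * (2.0 * st.th1(1) + 4.0 * st.th2(1));
  double M13 = EI / L0 * (4.0 * st.th1(2) + 2.0 * st.th2(2));
  double M23 = EI / L0 * (2.0 * st.th1(2) + 4.0 * st.th2(2));

  vec3 m1 = (-Mt) * e1 + M12 * e2 + M13 * e3;
  vec3 m2 = ( Mt) * e1 + M22 * e2 + M23 * e3;

  // Equilibrating shear from the bending-moment sums; the torsion pair cancels
  // in the frame-spin term so only bending contributes transverse force.
  double Sm2 = M12 + M22;
  double Sm3 = M13 + M23;
  vec3 f2 = N * e1 + (Sm2 / st.l) * e3 - (Sm3 / st.l) * e2;
  vec3 f1 = -f2;

  vec out(12);
  out.subvec(0, 2) = f1;
  out.subvec(3, 5) = m1;
  out.subvec(6, 8) = f2;
  out.subvec(9, 11) = m2;
  return out;
}

static double element_energy(const vec3& x1, const vec3& x2,
                             const mat33& R1, const mat33& R2,
                             const mat33& E0, double L0,
                             double EA, double EI, double GJ) {
  LocalState st = element_local_state(x1, x2, R1, R2, E0, L0);
  double a2 = st.th1(1), b2 = st.th2(1);
  double a3 = st.th1(2), b3 = st.th2(2);
  double dt = st.th2(0) - st.th1(0);
  double e_ax = 0.5 * EA * st.u * st.u / L0;
  double e_tw = 0.5 * GJ * dt * dt / L0;
  double e_b2 = (EI / L0) * (2.0 * a2 * a2 + 2.0 * b2 * b2 + 2.0 * a2 * b2);
  double e_b3 = (EI / L0) * (2.0 * a3 * a3 + 2.0 * b3 * b3 + 2.0 * a3 * b3);
  return e_ax + e_tw + e_b2 + e_b3;
}

static mat33 triad_slice(const cube& triads, uword i) { return triads.slice(i); }

// [[Rcpp::export]]
arma::vec rod_internal_force_cpp(const arma::mat& pos, const arma::cube& triads,
                                 const arma::cube& E0, const arma::vec& L0,
                                 double EA, double EI, double GJ) {
  uword n = pos.n_cols;
  vec f(6 * n, fill::zeros);
  for (uword e = 0; e + 1 < n; ++e) {
    vec fe = element_force(pos.col(e), pos.col(e + 1),
                           triad_slice(triads, e), triad_slice(triads, e + 1),
                           E0.slice(e), L0(e), EA, EI, GJ);
    f.subvec(6 * e, 6 * e + 5) += fe.subvec(0, 5);
    f.subvec(6 * (e + 1), 6 * (e + 1) + 5) += fe.subvec(6, 11);
  }
  return f;
}

// [[Rcpp::export]]
double rod_energy_cpp(const arma::mat& pos, const arma::cube& triads,
                      const arma::cube& E0, const arma::vec& L0,
                      double EA, double EI, double GJ) {
  uword n = pos.n_cols;
  double en = 0.0;
  for (uword e = 0; e + 1 < n; ++e) {
    en += element_energy(pos.col(e), pos.col(e + 1),
                         triad_slice(triads, e), triad_slice(triads, e + 1),
                         E0.slice(e), L0(e), EA, EI, GJ);
  }
  return en;
}

// Central finite-difference element tangent assembled into the global matrix.
// Rotational DOFs are perturbed multiplicatively: R -> exp(h e_k) R, matching
// the solver's update rule, so the tangent is consistent with it.
// [[Rcpp::export]]
arma::mat rod_tangent_cpp(const arma::mat& pos, const arma::cube& triads,
                          const arma::cube& E0, const arma::vec& L0,
                          double EA, double EI, double GJ, double h = 1e-6) {
  uword n = pos.n_cols;
  mat K(6 * n, 6 * n, fill::zeros);

  for (uword e = 0; e + 1 < n; ++e) {
    uvec gidx(12);
    for (uword k = 0; k < 6; ++k) {
      gidx(k) = 6 * e + k;
      gidx(6 + k) = 6 * (e + 1) + k;
    }
    mat Ke(12, 12, fill::zeros);
    for (uword j = 0; j < 12; ++j) {
      vec3 x1p = pos.col(e), x1m = pos.col(e);
      vec3 x2p = pos.col(e + 1), x2m = pos.col(e + 1);
      mat33 R1p = triad_slice(triads, e), R1m = R1p;
      mat33 R2p = triad_slice(triads, e + 1), R2m = R2p;
      uword node = j / 6, comp = j % 6;
      if (comp < 3) {
        if (node == 0) { x1p(comp) += h; x1m(comp) -= h; }
        else           { x2p(comp) += h; x2m(comp) -= h; }
      } else {
        vec3 w(fill::zeros);
        w(comp - 3) = h;
        mat33 dRp = exp_so3(w), dRm = exp_so3(-w);
        if (node == 0) { R1p = dRp * R1p; R1m = dRm * R1m; }
        else           { R2p = dRp * R2p; R2m = dRm * R2m; }
      }
      vec fp = element_force(x1p, x2p, R1p, R2p, E0.slice(e), L0(e), EA, EI, GJ);
      vec fm = element_force(x1m, x2m, R1m, R2m, E0.slice(e), L0(e), EA, EI, GJ);
      Ke.col(j) = (fp - fm) / (2.0 * h);
    }
    K.submat(gidx, gidx) += Ke;
  }
  return K;
}

// Apply incremental rotation vectors (3 x n) to nodal triads.
// [[Rcpp::export]]
arma::cube rod_update_triads_cpp(const arma::cube& triads, const arma::mat& dtheta) {
  cube out = triads;
  for (uword i = 0; i < triads.n_slices; ++i) {
    out.slice(i) = exp_so3(dtheta.col(i)) * out.slice(i);
  }
  return out;
}

// Rotation vector of each nodal triad (for twist/rotation diagnostics).
// [[Rcpp::export]]
arma::mat rod_triad_logs_cpp(const arma::cube& triads) {
  mat out(3, triads.n_slices);
  for (uword i = 0; i < triads.n_slices; ++i) {
    out.col(i) = log_so3(triads.slice(i));
  }
  return out;
}
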