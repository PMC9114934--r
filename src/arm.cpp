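// Rigid-body core for the 7-d.f. torque-controlled arm.
//
// Kinematic convention (fixed; see arm_model() docs): base frame at the
// shoulder, x forward, y lateral, z up.  Joint chain with local rotation
// axes and parent-frame offsets:
//   1 shoulder flexion/extension   axis y, offset 0
//   2 shoulder ab/adduction        axis x, offset 0
//   3 shoulder internal rotation   axis z, offset 0
//   4 elbow flexion                axis y, offset (0,0,-d1)
//   5 forearm pronation            axis x, offset 0
//   6 wrist flexion                axis y, offset (d2,0,0)
//   7 wrist deviation              axis z, offset 0
// fingertip reference point at (d3,0,0) in frame 7.  At the all-zero pose
// the upper arm hangs along -z, the forearm and hand point along +x
// (elbow bent 90 degrees).
//
// Inverse dynamics: recursive Newton-Euler.  Mass matrix: composite rigid
// bodies.  Integration: semi-implicit Euler with joint-limit clamping.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

inline void cross(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double dot(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
// r (3x3 row-major) * v
inline void matvec(const double r[9], const double v[3], double out[3]) {
  out[0] = r[0] * v[0] + r[1] * v[1] + r[2] * v[2];
  out[1] = r[3] * v[0] + r[4] * v[1] + r[5] * v[2];
  out[2] = r[6] * v[0] + r[7] * v[1] + r[8] * v[2];
}
inline void matmul(const double a[9], const double b[9], double out[9]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      out[3 * i + j] = a[3 * i] * b[j] + a[3 * i + 1] * b[3 + j] +
                       a[3 * i + 2] * b[6 + j];
}

struct ArmPar {
  double d[3];        // link lengths: shoulder-elbow, elbow-wrist, wrist-fingertip
  double mass[3];     // segment masses
  double inert[3][3]; // diagonal local inertia per segment
  double lo[7], hi[7];
  double grav[3];
  double tlim;
  double substep;
  double tilt;   // fixed forward mounting rotation of the shoulder (about y)
  double damp[7];  // viscous joint damping, N m s / rad
};

ArmPar parse_model(const List& model) {
  ArmPar p;
  NumericVector len = model["lengths"], mass = model["masses"],
                inertias = model["inertias"], lo = model["lower"],
                hi = model["upper"], g = model["gravity"];
  for (int i = 0; i < 3; ++i) {
    p.d[i] = len[i];
    p.mass[i] = mass[i];
    for (int j = 0; j < 3; ++j) p.inert[i][j] = inertias[3 * i + j];
    p.grav[i] = g[i];
  }
  for (int i = 0; i < 7; ++i) { p.lo[i] = lo[i]; p.hi[i] = hi[i]; }
  p.tlim = as<double>(model["torque_limit"]);
  p.substep = as<double>(model["integrator_substep"]);
  p.tilt = as<double>(model["shoulder_tilt"]);
  NumericVector dmp = model["joint_damping"];
  for (int i = 0; i < 7; ++i) p.damp[i] = dmp[i];
  return p;
}

// axis id per joint: 0=x,1=y,2=z
const int AXIS[7] = {1, 0, 2, 1, 0, 1, 2};
// body (segment) carried by each frame, -1 = massless
const int SEGOF[7] = {-1, -1, 0, -1, 1, -1, 2};

void joint_offset(const ArmPar& p, int i, double out[3]) {
  out[0] = out[1] = out[2] = 0.0;
  if (i == 3) out[2] = -p.d[0];   // elbow below shoulder in frame 3
  if (i == 5) out[0] = p.d[1];    // wrist ahead of elbow in frame 5
}
void com_local(const ArmPar& p, int seg, double out[3]) {
  out[0] = out[1] = out[2] = 0.0;
  if (seg == 0) out[2] = -0.5 * p.d[0];
  else out[0] = 0.5 * p.d[seg];
}

void axis_rot(int axis, double th, double r[9]) {
  double c = std::cos(th), s = std::sin(th);
  double id[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  for (int k = 0; k < 9; ++k) r[k] = id[k];
  if (axis == 0) { r[4] = c; r[5] = -s; r[7] = s; r[8] = c; }
  if (axis == 1) { r[0] = c; r[2] = s; r[6] = -s; r[8] = c; }
  if (axis == 2) { r[0] = c; r[1] = -s; r[3] = s; r[4] = c; }
}

void base_rot(const ArmPar& p, double r[9]) { axis_rot(1, p.tilt, r); }

struct Frames {
  double R[7][9];   // world rotation of frame i
  double o[7][3];   // world origin of frame i
  double z[7][3];   // world joint axis
  double cw[7][3];  // world COM of the body at frame i (if any)
  double Iw[7][9];  // world inertia of that body about its COM
};

void fk_frames(const ArmPar& p, const double* q, Frames& F) {
  double Rprev[9];
  base_rot(p, Rprev);
  double oprev[3] = {0, 0, 0};
  for (int i = 0; i < 7; ++i) {
    double off[3], d[3], Rl[9];
    joint_offset(p, i, off);
    matvec(Rprev, off, d);
    for (int k = 0; k < 3; ++k) F.o[i][k] = oprev[k] + d[k];
    axis_rot(AXIS[i], q[i], Rl);
    matmul(Rprev, Rl, F.R[i]);
    double a[3] = {0, 0, 0};
    a[AXIS[i]] = 1.0;
    matvec(F.R[i], a, F.z[i]);
    int seg = SEGOF[i];
    if (seg >= 0) {
      double cl[3], rc[3];
      com_local(p, seg, cl);
      matvec(F.R[i], cl, rc);
      for (int k = 0; k < 3; ++k) F.cw[i][k] = F.o[i][k] + rc[k];
      // Iw = R * diag(I) * R^T
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c) {
          double s = 0;
          for (int k = 0; k < 3; ++k)
            s += F.R[i][3 * r + k] * p.inert[seg][k] * F.R[i][3 * c + k];
          F.Iw[i][3 * r + c] = s;
        }
    }
    for (int k = 0; k < 9; ++k) Rprev[k] = F.R[i][k];
    for (int k = 0; k < 3; ++k) oprev[k] = F.o[i][k];
  }
}

void fingertip(const ArmPar& p, const Frames& F, double out[3]) {
  double tl[3] = {p.d[2], 0, 0}, tw[3];
  matvec(F.R[6], tl, tw);
  for (int k = 0; k < 3; ++k) out[k] = F.o[6][k] + tw[k];
}

// Recursive Newton-Euler: joint torques realizing qdd at (q, qd).
void rnea(const ArmPar& p, const double* q, const double* qd,
          const double* qdd, bool gravity, double* tau) {
  Frames F;
  fk_frames(p, q, F);
  double w[7][3], wd[7][3], ao[7][3];
  double wprev[3] = {0, 0, 0}, wdprev[3] = {0, 0, 0};
  double aoprev[3] = {0, 0, 0};
  if (gravity) for (int k = 0; k < 3; ++k) aoprev[k] = -p.grav[k];
  double Rprev[9];
  base_rot(p, Rprev);
  double Fb[7][3], Nb[7][3], rc[7][3];
  for (int i = 0; i < 7; ++i) {
    double off[3], d[3];
    joint_offset(p, i, off);
    matvec(Rprev, off, d);
    double t1[3], t2[3], t3[3];
    cross(wdprev, d, t1);
    cross(wprev, d, t2);
    cross(wprev, t2, t3);
    double aoi[3];
    for (int k = 0; k < 3; ++k) aoi[k] = aoprev[k] + t1[k] + t3[k];
    double zqd[3], zqdd[3];
    for (int k = 0; k < 3; ++k) {
      zqd[k] = F.z[i][k] * qd[i];
      zqdd[k] = F.z[i][k] * qdd[i];
    }
    double wxz[3];
    cross(wprev, zqd, wxz);
    for (int k = 0; k < 3; ++k) {
      w[i][k] = wprev[k] + zqd[k];
      wd[i][k] = wdprev[k] + zqdd[k] + wxz[k];
      ao[i][k] = aoi[k];
    }
    int seg = SEGOF[i];
    if (seg >= 0) {
      double cl[3];
      com_local(p, seg, cl);
      matvec(F.R[i], cl, rc[i]);
      double u1[3], u2[3], u3[3], acom[3];
      cross(wd[i], rc[i], u1);
      cross(w[i], rc[i], u2);
      cross(w[i], u2, u3);
      for (int k = 0; k < 3; ++k) acom[k] = ao[i][k] + u1[k] + u3[k];
      for (int k = 0; k < 3; ++k) Fb[i][k] = p.mass[seg] * acom[k];
      double Iw_wd[3], Iw_w[3], wIw[3];
      matvec(F.Iw[i], wd[i], Iw_wd);
      matvec(F.Iw[i], w[i], Iw_w);
      cross(w[i], Iw_w, wIw);
      for (int k = 0; k < 3; ++k) Nb[i][k] = Iw_wd[k] + wIw[k];
    } else {
      for (int k = 0; k < 3; ++k) { Fb[i][k] = 0; Nb[i][k] = 0; rc[i][k] = 0; }
    }
    for (int k = 0; k < 9; ++k) Rprev[k] = F.R[i][k];
    for (int k = 0; k < 3; ++k) { wprev[k] = w[i][k]; wdprev[k] = wd[i][k];
                                  aoprev[k] = ao[i][k]; }
  }
  double fch[3] = {0, 0, 0}, nch[3] = {0, 0, 0};
  for (int i = 6; i >= 0; --i) {
    double f[3], n[3], t1[3], t2[3];
    cross(rc[i], Fb[i], t1);
    double dch[3] = {0, 0, 0};
    if (i < 6) {
      double off[3];
      joint_offset(p, i + 1, off);
      matvec(F.R[i], off, dch);
    }
    cross(dch, fch, t2);
    for (int k = 0; k < 3; ++k) {
      f[k] = Fb[i][k] + fch[k];
      n[k] = Nb[i][k] + nch[k] + t1[k] + t2[k];
    }
    tau[i] = dot(F.z[i], n) + p.damp[i] * qd[i];
    for (int k = 0; k < 3; ++k) { fch[k] = f[k]; nch[k] = n[k]; }
  }
}

// Composite-rigid-body mass matrix.
void mass_matrix(const ArmPar& p, const double* q, double M[7][7]) {
  Frames F;
  fk_frames(p, q, F);
  double mc[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  double cc[8][3], Ic[8][9];
  for (int k = 0; k < 3; ++k) cc[7][k] = 0;
  for (int k = 0; k < 9; ++k) Ic[7][k] = 0;
  for (int i = 6; i >= 0; --i) {
    int seg = SEGOF[i];
    double mi = seg >= 0 ? p.mass[seg] : 0.0;
    double mtot = mi + mc[i + 1];
    double com[3] = {0, 0, 0};
    if (mtot > 0)
      for (int k = 0; k < 3; ++k)
        com[k] = (mi * (seg >= 0 ? F.cw[i][k] : 0.0) +
                  mc[i + 1] * cc[i + 1][k]) / mtot;
    double I[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    if (seg >= 0) {
      double dvec[3];
      for (int k = 0; k < 3; ++k) dvec[k] = F.cw[i][k] - com[k];
      double d2 = dot(dvec, dvec);
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          I[3 * r + c] += F.Iw[i][3 * r + c] +
                          mi * ((r == c ? d2 : 0.0) - dvec[r] * dvec[c]);
    }
    if (mc[i + 1] > 0) {
      double dvec[3];
      for (int k = 0; k < 3; ++k) dvec[k] = cc[i + 1][k] - com[k];
      double d2 = dot(dvec, dvec);
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          I[3 * r + c] += Ic[i + 1][3 * r + c] +
                          mc[i + 1] * ((r == c ? d2 : 0.0) - dvec[r] * dvec[c]);
    }
    mc[i] = mtot;
    for (int k = 0; k < 3; ++k) cc[i][k] = com[k];
    for (int k = 0; k < 9; ++k) Ic[i][k] = I[k];
  }
  for (int i = 0; i < 7; ++i) {
    // unit acceleration at joint i, zero velocity: composite i reacts
    double r[3], acom[3], Fv[3], Nv[3];
    for (int k = 0; k < 3; ++k) r[k] = cc[i][k] - F.o[i][k];
    cross(F.z[i], r, acom);
    for (int k = 0; k < 3; ++k) Fv[k] = mc[i] * acom[k];
    matvec(Ic[i], F.z[i], Nv);
    for (int j = 0; j <= i; ++j) {
      double rj[3], t[3], n[3];
      for (int k = 0; k < 3; ++k) rj[k] = cc[i][k] - F.o[j][k];
      cross(rj, Fv, t);
      for (int k = 0; k < 3; ++k) n[k] = Nv[k] + t[k];
      M[j][i] = M[i][j] = dot(F.z[j], n);
    }
  }
}

// Cholesky solve M x = b for the free-joint submatrix.
bool chol_solve(double M[7][7], const double* b, const int* idx, int n,
                double* x) {
  double A[7][7], L[7][7], y[7];
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) A[i][j] = M[idx[i]][idx[j]];
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) L[i][j] = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      if (i == j) {
        if (s <= 1e-14) return false;
        L[i][i] = std::sqrt(s);
      } else {
        L[i][j] = s / L[j][j];
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    double s = b[idx[i]];
    for (int k = 0; k < i; ++k) s -= L[i][k] * y[k];
    y[i] = s / L[i][i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = y[i];
    for (int k = i + 1; k < n; ++k) s -= L[k][i] * x[k];
    x[i] = s / L[i][i];
  }
  return true;
}

// forward dynamics: qdd from (q, qd, tau); locked joints held still.
// himp > 0 treats viscous damping implicitly over that horizon (adds
// himp * b_i to the mass-matrix diagonal), which keeps the light wrist
// joints unconditionally stable during integration.
bool fwd_dyn(const ArmPar& p, const double* q, const double* qd,
             const double* tau, const bool* locked, double* qdd,
             double himp) {
  double bias[7], zero[7] = {0, 0, 0, 0, 0, 0, 0};
  rnea(p, q, qd, zero, true, bias);
  double M[7][7], rhs[7];
  mass_matrix(p, q, M);
  for (int i = 0; i < 7; ++i) {
    rhs[i] = tau[i] - bias[i];
    M[i][i] += himp * p.damp[i];
  }
  int idx[7], n = 0;
  for (int i = 0; i < 7; ++i) {
    qdd[i] = 0;
    if (!locked || !locked[i]) idx[n++] = i;
  }
  double x[7];
  if (!chol_solve(M, rhs, idx, n, x)) return false;
  for (int i = 0; i < n; ++i) qdd[idx[i]] = x[i];
  return true;
}

// one control interval of dt seconds; returns false on divergence.
bool step_state(const ArmPar& p, double* q, double* qd, const double* tau_in,
                const bool* locked, double dt) {
  double tau[7];
  for (int i = 0; i < 7; ++i) {
    double t = tau_in[i];
    if (t > p.tlim) t = p.tlim;
    if (t < -p.tlim) t = -p.tlim;
    tau[i] = t;
  }
  int nsub = (int)std::lround(dt / p.substep);
  if (nsub < 1) nsub = 1;
  double h = dt / nsub;
  for (int s = 0; s < nsub; ++s) {
    double qdd[7];
    if (!fwd_dyn(p, q, qd, tau, locked, qdd, h)) return false;
    for (int i = 0; i < 7; ++i) {
      if (locked && locked[i]) continue;
      qd[i] += h * qdd[i];
      q[i] += h * qd[i];
      if (q[i] < p.lo[i]) { q[i] = p.lo[i]; if (qd[i] < 0) qd[i] = 0; }
      if (q[i] > p.hi[i]) { q[i] = p.hi[i]; if (qd[i] > 0) qd[i] = 0; }
      if (!std::isfinite(q[i]) || !std::isfinite(qd[i]) ||
          std::fabs(qd[i]) > 1e6)
        return false;
    }
  }
  return true;
}

void tip_vel(const ArmPar& p, const Frames& F, const double* qd,
             const double tip[3], double out[3]) {
  out[0] = out[1] = out[2] = 0;
  for (int i = 0; i < 7; ++i) {
    double r[3], c[3];
    for (int k = 0; k < 3; ++k) r[k] = tip[k] - F.o[i][k];
    cross(F.z[i], r, c);
    for (int k = 0; k < 3; ++k) out[k] += c[k] * qd[i];
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector arm_fk_cpp(List model, NumericVector q) {
  ArmPar p = parse_model(model);
  Frames F;
  fk_frames(p, REAL(q), F);
  double tip[3];
  fingertip(p, F, tip);
  return NumericVector::create(tip[0], tip[1], tip[2]);
}

// [[Rcpp::export]]
NumericMatrix arm_jacobian_cpp(List model, NumericVector q) {
  ArmPar p = parse_model(model);
  Frames F;
  fk_frames(p, REAL(q), F);
  double tip[3];
  fingertip(p, F, tip);
  NumericMatrix J(3, 7);
  for (int i = 0; i < 7; ++i) {
    double r[3], c[3];
    for (int k = 0; k < 3; ++k) r[k] = tip[k] - F.o[i][k];
    cross(F.z[i], r, c);
    for (int k = 0; k < 3; ++k) J(k, i) = c[k];
  }
  return J;
}

// [[Rcpp::export]]
NumericVector arm_rnea_cpp(List model, NumericVector q, NumericVector qd,
                           NumericVector qdd, bool gravity) {
  ArmPar p = parse_model(model);
  NumericVector tau(7);
  rnea(p, REAL(q), REAL(qd), REAL(qdd), gravity, REAL(tau));
  return tau;
}

// [[Rcpp::export]]
NumericMatrix arm_mass_matrix_cpp(List model, NumericVector q) {
  ArmPar p = parse_model(model);
  double M[7][7];
  mass_matrix(p, REAL(q), M);
  NumericMatrix out(7, 7);
  for (int i = 0; i < 7; ++i)
    for (int j = 0; j < 7; ++j) out(i, j) = M[i][j];
  return out;
}

// [[Rcpp::export]]
NumericVector arm_fd_cpp(List model, NumericVector q, NumericVector qd,
                         NumericVector tau) {
  ArmPar p = parse_model(model);
  NumericVector qdd(7);
  if (!fwd_dyn(p, REAL(q), REAL(qd), REAL(tau), nullptr, REAL(qdd), 0.0))
    stop("simulation diverged: singular mass matrix");
  return qdd;
}

// [[Rcpp::export]]
List arm_step_cpp(List model, NumericVector q, NumericVector qd,
                  NumericVector tau, double dt, LogicalVector locked) {
  ArmPar p = parse_model(model);
  double qs[7], qds[7];
  bool lk[7];
  bool any_lock = locked.size() == 7;
  for (int i = 0; i < 7; ++i) {
    qs[i] = q[i];
    qds[i] = qd[i];
    lk[i] = any_lock ? (bool)locked[i] : false;
  }
  bool ok = step_state(p, qs, qds, REAL(tau), any_lock ? lk : nullptr, dt);
  return List::create(_["q"] = NumericVector(qs, qs + 7),
                      _["qd"] = NumericVector(qds, qds + 7),
                      _["ok"] = ok);
}

// [[Rcpp::export]]
List arm_rollout_cpp(List model, NumericVector q0, NumericVector qd0,
                     NumericMatrix torques, double dt) {
  ArmPar p = parse_model(model);
  int T = torques.nrow();
  NumericMatrix q_pre(T, 7), qd_pre(T, 7), tip_post(T, 3), tipvel_post(T, 3);
  double q[7], qd[7];
  for (int i = 0; i < 7; ++i) { q[i] = q0[i]; qd[i] = qd0[i]; }
  bool ok = true;
  int t_done = 0;
  for (int t = 0; t < T; ++t) {
    double tau[7];
    for (int i = 0; i < 7; ++i) {
      q_pre(t, i) = q[i];
      qd_pre(t, i) = qd[i];
      tau[i] = torques(t, i);
    }
    if (!step_state(p, q, qd, tau, nullptr, dt)) { ok = false; break; }
    Frames F;
    fk_frames(p, q, F);
    double tip[3], tv[3];
    fingertip(p, F, tip);
    tip_vel(p, F, qd, tip, tv);
    for (int k = 0; k < 3; ++k) {
      tip_post(t, k) = tip[k];
      tipvel_post(t, k) = tv[k];
    }
    t_done = t + 1;
  }
  return List::create(
      _["q_pre"] = q_pre, _["qd_pre"] = qd_pre, _["tip"] = tip_post,
      _["tip_vel"] = tipvel_post, _["q_final"] = NumericVector(q, q + 7),
      _["qd_final"] = NumericVector(qd, qd + 7), _["ok"] = ok,
      _["t_done"] = t_done);
}

// [[Rcpp::export]]
List arm_energy_cpp(List model, NumericVector q, NumericVector qd) {
  ArmPar p = parse_model(model);
  Frames F;
  fk_frames(p, REAL(q), F);
  double w[3] = {0, 0, 0}, vo[3] = {0, 0, 0};
  double Rprev[9];
  base_rot(p, Rprev);
  double oprev[3] = {0, 0, 0};
  double ke = 0, pe = 0;
  for (int i = 0; i < 7; ++i) {
    double off[3], dvec[3], t[3];
    joint_offset(p, i, off);
    matvec(Rprev, off, dvec);
    cross(w, dvec, t);
    for (int k = 0; k < 3; ++k) vo[k] += t[k];
    for (int k = 0; k < 3; ++k) w[k] += F.z[i][k] * qd[i];
    int seg = SEGOF[i];
    if (seg >= 0) {
      double cl[3], rc[3], u[3], vc[3];
      com_local(p, seg, cl);
      matvec(F.R[i], cl, rc);
      cross(w, rc, u);
      for (int k = 0; k < 3; ++k) vc[k] = vo[k] + u[k];
      double Iw_w[3];
      matvec(F.Iw[i], w, Iw_w);
      ke += 0.5 * p.mass[seg] * dot(vc, vc) + 0.5 * dot(w, Iw_w);
      pe -= p.mass[seg] * dot(p.grav, F.cw[i]);
    }
    for (int k = 0; k < 9; ++k) Rprev[k] = F.R[i][k];
    for (int k = 0; k < 3; ++k) oprev[k] = F.o[i][k];
  }
  (void)oprev;
  return List::create(_["kinetic"] = ke, _["potential"] = pe,
                      _["total"] = ke + pe);
}
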