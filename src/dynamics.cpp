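// Planar (sagittal) floating-base biped dynamics.
//
// Generalized coordinates q (9): root x, root z, trunk pitch,
// hipL, kneeL, ankleL, hipR, kneeR, ankleR.
// Segment absolute orientations are signed sums of the angle coordinates
// (trunk pitch plus the relative joint angles along the chain); knee flexion
// is positive, so the shank orientation subtracts the knee angle.
//
// Equations of motion are assembled with point Jacobians:
//   M(q) qdd = Q_applied + Q_gravity + Q_contact - sum_s m_s J_s^T (Jdot_s qd)
// and integrated with a semi-implicit Euler step.

#include <RcppArmadillo.h>
using namespace Rcpp;

static const int N_SEG = 7;   // trunk, thighL, shankL, footL, thighR, shankR, footR
static const int N_Q = 9;
static const int N_CPT = 4;   // heelL, toeL, heelR, toeR

// signed incidence of segment orientation on angle coords
// cols: pitch, hipL, kneeL, ankleL, hipR, kneeR, ankleR
static const double A_INC[N_SEG][7] = {
  {1, 0, 0, 0, 0, 0, 0},
  {1, 1, 0, 0, 0, 0, 0},
  {1, 1, -1, 0, 0, 0, 0},
  {1, 1, -1, 1, 0, 0, 0},
  {1, 0, 0, 0, 1, 0, 0},
  {1, 0, 0, 0, 1, -1, 0},
  {1, 0, 0, 0, 1, -1, 1}};

// pivot point index per angle coord: 0 root, 1 kneeL, 2 ankleL, 3 kneeR, 4 ankleR
static const int PIVOT[7] = {0, 0, 1, 2, 0, 3, 4};
static const int CPT_SEG[N_CPT] = {3, 3, 6, 6};

struct Biped {
  arma::vec m;       // 7 segment masses
  arma::vec I;       // 7 moments of inertia about segment CoM
  arma::mat com;     // 7 x 2 CoM offsets in segment frame (from proximal point)
  double l_th, l_sh; // thigh, shank lengths
  arma::mat cpt;     // 2 x 2 contact point offsets in foot frame (heel, toe)
  arma::vec jlo, jhi;
  double limk, limd; // one-sided joint-limit spring/damper
  double g;
};

struct ContactParams {
  double kn, cn, mu, veps;
};

static Biped unpack_model(const List& model) {
  Biped b;
  b.m = as<arma::vec>(model["seg_mass"]);
  b.I = as<arma::vec>(model["seg_inertia"]);
  b.com = as<arma::mat>(model["com_local"]);
  b.l_th = as<double>(model["l_thigh"]);
  b.l_sh = as<double>(model["l_shank"]);
  b.cpt = as<arma::mat>(model["contact_local"]);
  b.jlo = as<arma::vec>(model["joint_lo"]);
  b.jhi = as<arma::vec>(model["joint_hi"]);
  b.limk = as<double>(model["limit_stiffness"]);
  b.limd = as<double>(model["limit_damping"]);
  b.g = as<double>(model["gravity"]);
  return b;
}

struct Kin {
  double alpha[N_SEG];           // segment orientations
  double piv[5][2];              // root, kneeL, ankleL, kneeR, ankleR
  double P[N_SEG][2];            // segment CoM positions
  double C[N_CPT][2];            // contact point positions
};

static inline void rot(double a, double x, double z, double out[2]) {
  double c = std::cos(a), s = std::sin(a);
  out[0] = c * x - s * z;
  out[1] = s * x + c * z;
}

static void fk(const Biped& b, const arma::vec& q, Kin& k) {
  for (int s = 0; s < N_SEG; ++s) {
    double a = 0.0;
    for (int j = 0; j < 7; ++j) a += A_INC[s][j] * q(2 + j);
    k.alpha[s] = a;
  }
  k.piv[0][0] = q(0); k.piv[0][1] = q(1);
  double v[2];
  // left leg joints
  rot(k.alpha[1], 0.0, -b.l_th, v);
  k.piv[1][0] = q(0) + v[0]; k.piv[1][1] = q(1) + v[1];
  rot(k.alpha[2], 0.0, -b.l_sh, v);
  k.piv[2][0] = k.piv[1][0] + v[0]; k.piv[2][1] = k.piv[1][1] + v[1];
  // right leg joints
  rot(k.alpha[4], 0.0, -b.l_th, v);
  k.piv[3][0] = q(0) + v[0]; k.piv[3][1] = q(1) + v[1];
  rot(k.alpha[5], 0.0, -b.l_sh, v);
  k.piv[4][0] = k.piv[3][0] + v[0]; k.piv[4][1] = k.piv[3][1] + v[1];
  // segment CoMs: proximal points are root, root, kneeL, ankleL, root, kneeR, ankleR
  static const int PROX[N_SEG] = {0, 0, 1, 2, 0, 3, 4};
  for (int s = 0; s < N_SEG; ++s) {
    rot(k.alpha[s], b.com(s, 0), b.com(s, 1), v);
    k.P[s][0] = k.piv[PROX[s]][0] + v[0];
    k.P[s][1] = k.piv[PROX[s]][1] + v[1];
  }
  // contact points on the feet
  for (int i = 0; i < N_CPT; ++i) {
    int s = CPT_SEG[i];
    int ankle = (s == 3) ? 2 : 4;
    rot(k.alpha[s], b.cpt(i % 2, 0), b.cpt(i % 2, 1), v);
    k.C[i][0] = k.piv[ankle][0] + v[0];
    k.C[i][1] = k.piv[ankle][1] + v[1];
  }
}

// Jacobian of a point attached to segment s (2 x 9, dense in a fixed mat)
static void point_jac(const Kin& k, int s, const double p[2], arma::mat& J) {
  J.zeros(2, N_Q);
  J(0, 0) = 1.0;
  J(1, 1) = 1.0;
  for (int j = 0; j < 7; ++j) {
    double c = A_INC[s][j];
    if (c != 0.0) {
      const double* piv = k.piv[PIVOT[j]];
      J(0, 2 + j) = -c * (p[1] - piv[1]);
      J(1, 2 + j) = c * (p[0] - piv[0]);
    }
  }
}

static arma::mat mass_matrix_internal(const Biped& b, const Kin& k) {
  arma::mat M(N_Q, N_Q, arma::fill::zeros);
  arma::mat J(2, N_Q);
  for (int s = 0; s < N_SEG; ++s) {
    point_jac(k, s, k.P[s], J);
    M += b.m(s) * (J.t() * J);
    arma::vec bvec(N_Q, arma::fill::zeros);
    for (int j = 0; j < 7; ++j) bvec(2 + j) = A_INC[s][j];
    M += b.I(s) * (bvec * bvec.t());
  }
  return M;
}

// contact force at a point: penalty normal, tanh-regularized Coulomb friction
static inline void contact_force_point(const ContactParams& cp, double mu,
                                       double pz, double vx, double vz,
                                       double surf_h, double surf_vx,
                                       double f[2]) {
  double pen = surf_h - pz;
  if (pen <= 0.0) { f[0] = 0.0; f[1] = 0.0; return; }
  double pendot = -vz;
  double fn = cp.kn * pen * (1.0 + cp.cn * pendot);
  if (fn < 0.0) fn = 0.0;
  double vrel = vx - surf_vx;
  double ft = -mu * fn * std::tanh(vrel / cp.veps);
  f[0] = ft;
  f[1] = fn;
}

// Assemble generalized forces and accelerations.  Returns qdd; contactF (4x2)
// receives the per-point forces, loads (fT_sum, fN_sum) the totals on the surface.
static arma::vec dynamics_qdd(const Biped& b, const arma::vec& q, const arma::vec& qd,
                              const arma::vec& tau6, double fz_ext, double my_ext,
                              const ContactParams& cp, double mu_contact,
                              double surf_h, double surf_vx,
                              bool pin_root,
                              arma::mat& contactF, double loads[2]) {
  Kin k;
  fk(b, q, k);
  arma::mat M = mass_matrix_internal(b, k);
  arma::vec Q(N_Q, arma::fill::zeros);
  arma::mat J(2, N_Q);

  // pivot velocities
  double pv[5][2];
  pv[0][0] = qd(0); pv[0][1] = qd(1);
  double w_thL = qd(2) + qd(3);
  double w_shL = w_thL - qd(4);
  double w_thR = qd(2) + qd(6);
  double w_shR = w_thR - qd(7);
  pv[1][0] = qd(0) - w_thL * (k.piv[1][1] - q(1));
  pv[1][1] = qd(1) + w_thL * (k.piv[1][0] - q(0));
  pv[2][0] = pv[1][0] - w_shL * (k.piv[2][1] - k.piv[1][1]);
  pv[2][1] = pv[1][1] + w_shL * (k.piv[2][0] - k.piv[1][0]);
  pv[3][0] = qd(0) - w_thR * (k.piv[3][1] - q(1));
  pv[3][1] = qd(1) + w_thR * (k.piv[3][0] - q(0));
  pv[4][0] = pv[3][0] - w_shR * (k.piv[4][1] - k.piv[3][1]);
  pv[4][1] = pv[3][1] + w_shR * (k.piv[4][0] - k.piv[3][0]);

  // gravity, velocity-product terms per segment
  for (int s = 0; s < N_SEG; ++s) {
    point_jac(k, s, k.P[s], J);
    arma::vec v = J * qd;
    double omega = 0.0;
    for (int j = 0; j < 7; ++j) omega += A_INC[s][j] * qd(2 + j);
    double w[2] = {0.0, 0.0};
    for (int j = 0; j < 7; ++j) {
      double c = A_INC[s][j] * qd(2 + j);
      if (c != 0.0) {
        w[0] += c * pv[PIVOT[j]][0];
        w[1] += c * pv[PIVOT[j]][1];
      }
    }
    // Jdot*qd = S(omega * v - w), S(a) = (-a_z, a_x)
    double ax = -(omega * v(1) - w[1]);
    double az = (omega * v(0) - w[0]);
    arma::vec f(2);
    f(0) = -b.m(s) * ax;
    f(1) = -b.m(s) * az - b.m(s) * b.g;
    Q += J.t() * f;
  }

  // contact
  loads[0] = 0.0; loads[1] = 0.0;
  for (int i = 0; i < N_CPT; ++i) {
    int s = CPT_SEG[i];
    point_jac(k, s, k.C[i], J);
    arma::vec v = J * qd;
    double f[2];
    contact_force_point(cp, mu_contact, k.C[i][1], v(0), v(1), surf_h, surf_vx, f);
    contactF(i, 0) = f[0];
    contactF(i, 1) = f[1];
    if (f[1] != 0.0 || f[0] != 0.0) {
      arma::vec fv(2); fv(0) = f[0]; fv(1) = f[1];
      Q += J.t() * fv;
      loads[0] += f[0];
      loads[1] += f[1];
    }
  }

  // joint torques and one-sided limit springs
  for (int j = 0; j < 6; ++j) {
    double tq = tau6(j);
    double qj = q(3 + j);
    if (qj < b.jlo(j)) tq += b.limk * (b.jlo(j) - qj) - b.limd * qd(3 + j);
    if (qj > b.jhi(j)) tq += b.limk * (b.jhi(j) - qj) - b.limd * qd(3 + j);
    Q(3 + j) += tq;
  }

  // external root wrench (vertical force + pitch torque; never horizontal)
  Q(1) += fz_ext;
  Q(2) += my_ext;

  arma::vec qdd(N_Q, arma::fill::zeros);
  if (pin_root) {
    arma::uvec idx = arma::regspace<arma::uvec>(3, N_Q - 1);
    arma::vec sol = arma::solve(M.submat(idx, idx), Q.elem(idx),
                                arma::solve_opts::likely_sympd);
    qdd.elem(idx) = sol;
  } else {
    qdd = arma::solve(M, Q, arma::solve_opts::likely_sympd);
  }
  return qdd;
}

// [[Rcpp::export]]
arma::mat cpp_mass_matrix(const List& model, const arma::vec& q) {
  Biped b = unpack_model(model);
  Kin k;
  fk(b, q, k);
  return mass_matrix_internal(b, k);
}

// [[Rcpp::export]]
List cpp_fk(const List& model, const arma::vec& q) {
  Biped b = unpack_model(model);
  Kin k;
  fk(b, q, k);
  arma::mat joints(5, 2), coms(N_SEG, 2), cpts(N_CPT, 2);
  for (int i = 0; i < 5; ++i) { joints(i, 0) = k.piv[i][0]; joints(i, 1) = k.piv[i][1]; }
  for (int s = 0; s < N_SEG; ++s) { coms(s, 0) = k.P[s][0]; coms(s, 1) = k.P[s][1]; }
  for (int i = 0; i < N_CPT; ++i) { cpts(i, 0) = k.C[i][0]; cpts(i, 1) = k.C[i][1]; }
  double mtot = arma::accu(b.m);
  arma::rowvec com = (b.m.t() * coms) / mtot;
  return List::create(_["joints"] = joints, _["seg_coms"] = coms,
                      _["contacts"] = cpts, _["com"] = arma::vec(com.t()));
}

// [[Rcpp::export]]
List cpp_contact_forces(const List& model, const arma::vec& q, const arma::vec& qd,
                        double surf_h, double surf_vx, double mu,
                        double kn, double cn, double veps) {
  Biped b = unpack_model(model);
  ContactParams cp; cp.kn = kn; cp.cn = cn; cp.mu = mu; cp.veps = veps;
  Kin k;
  fk(b, q, k);
  arma::mat F(N_CPT, 2, arma::fill::zeros);
  arma::mat J(2, N_Q);
  double loads[2] = {0.0, 0.0};
  for (int i = 0; i < N_CPT; ++i) {
    point_jac(k, CPT_SEG[i], k.C[i], J);
    arma::vec v = J * qd;
    double f[2];
    contact_force_point(cp, mu, k.C[i][1], v(0), v(1), surf_h, surf_vx, f);
    F(i, 0) = f[0]; F(i, 1) = f[1];
    loads[0] += f[0]; loads[1] += f[1];
  }
  return List::create(_["forces"] = F,
                      _["surface_load_tangential"] = -loads[0],
                      _["surface_load_vertical"] = -loads[1]);
}

// [[Rcpp::export]]
List cpp_step(const List& model, const arma::vec& q, const arma::vec& qd,
              const arma::vec& tau6, double fz_ext, double my_ext,
              double surf_h, double surf_vx, double mu,
              double kn, double cn, double veps, double dt,
              bool pin_root = false) {
  Biped b = unpack_model(model);
  ContactParams cp; cp.kn = kn; cp.cn = cn; cp.mu = mu; cp.veps = veps;
  if (!q.is_finite()) stop("numeric failure: non-finite generalized coordinates (q)");
  if (!qd.is_finite()) stop("numeric failure: non-finite generalized velocities (qd)");
  arma::mat contactF(N_CPT, 2, arma::fill::zeros);
  double loads[2];
  arma::vec qdd = dynamics_qdd(b, q, qd, tau6, fz_ext, my_ext, cp, mu,
                               surf_h, surf_vx, pin_root, contactF, loads);
  if (!qdd.is_finite()) stop("numeric failure: non-finite accelerations (qdd)");
  arma::vec qd2 = qd + dt * qdd;
  if (pin_root) qd2.subvec(0, 2).zeros();
  arma::vec q2 = q + dt * qd2;
  return List::create(_["q"] = q2, _["qd"] = qd2, _["contact_forces"] = contactF,
                      _["surface_load_tangential"] = -loads[0],
                      _["surface_load_vertical"] = -loads[1]);
}

// [[Rcpp::export]]
double cpp_energy(const List& model, const arma::vec& q, const arma::vec& qd) {
  Biped b = unpack_model(model);
  Kin k;
  fk(b, q, k);
  arma::mat M = mass_matrix_internal(b, k);
  double ke = 0.5 * arma::as_scalar(qd.t() * M * qd);
  double pe = 0.0;
  for (int s = 0; s < N_SEG; ++s) pe += b.m(s) * b.g * k.P[s][1];
  return ke + pe;
}

// Full trial loop: reference-tracking joint PD + root stabilizer + surface
// (ground, ideal belt, or PD-speed-controlled belt), logged every step.
// treadmill_mode: 0 overground, 1 ideal belt, 2 PD belt.
// [[Rcpp::export]]
List cpp_simulate(const List& model,
                  const arma::vec& q0, const arma::vec& qd0,
                  const arma::mat& ref_ang,   // n_ref x 6 (phase-uniform incl. endpoint)
                  const arma::mat& ref_vel,   // n_ref x 6
                  const arma::vec& ref_rootz, const arma::vec& ref_rootzd,
                  const arma::vec& ref_pitch, const arma::vec& ref_pitchd,
                  double cycle_T, double phase0,
                  const arma::vec& kp6, const arma::vec& kd6, double tau_max,
                  double phase_lead,
                  bool stab_on, double stab_kp_pitch, double stab_kd_pitch,
                  double stab_kp_z, double stab_kd_z,
                  int treadmill_mode, double v_target, double f_max,
                  double f_ctrl, double belt_kp, double belt_kd,
                  double m_belt, double mu_deck, double belt_v0,
                  double mu, double kn, double cn, double veps,
                  double dt, int n_steps) {
  Biped b = unpack_model(model);
  ContactParams cp; cp.kn = kn; cp.cn = cn; cp.mu = mu; cp.veps = veps;
  const int n_ref = ref_ang.n_rows;

  arma::vec q = q0, qd = qd0;
  double belt_pos = 0.0, belt_v = belt_v0, belt_F = 0.0;
  double next_update = 0.0, prev_v_update = belt_v0;
  bool have_prev = false;
  double period = (f_ctrl > 0.0) ? 1.0 / f_ctrl : 0.0;

  // log: t, q(9), qd(9), cpt forces fx fz x4 (8), belt pos/vel/force (3) = 30
  const int NC = 30;
  arma::mat log(n_steps, NC, arma::fill::zeros);
  arma::mat contactF(N_CPT, 2, arma::fill::zeros);
  double loads[2];
  arma::vec tau(6);
  int status = 0;
  int done = 0;

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    // gait phase and reference interpolation
    double phx = phase0 + t / cycle_T;
    double ph = phx - std::floor(phx);
    double x = ph * (n_ref - 1);
    int i0 = (int)std::floor(x);
    if (i0 > n_ref - 2) i0 = n_ref - 2;
    double fr = x - i0;
    // joint targets taken slightly ahead in phase to compensate PD lag
    double phl = phx + phase_lead / cycle_T;
    phl -= std::floor(phl);
    double xl = phl * (n_ref - 1);
    int i0l = (int)std::floor(xl);
    if (i0l > n_ref - 2) i0l = n_ref - 2;
    double frl = xl - i0l;
    for (int j = 0; j < 6; ++j) {
      double tgt = (1 - frl) * ref_ang(i0l, j) + frl * ref_ang(i0l + 1, j);
      double tq = kp6(j) * (tgt - q(3 + j)) - kd6(j) * qd(3 + j);
      if (tq > tau_max) tq = tau_max;
      if (tq < -tau_max) tq = -tau_max;
      tau(j) = tq;
    }
    double fz_ext = 0.0, my_ext = 0.0;
    if (stab_on) {
      double zr = (1 - fr) * ref_rootz(i0) + fr * ref_rootz(i0 + 1);
      double zdr = (1 - fr) * ref_rootzd(i0) + fr * ref_rootzd(i0 + 1);
      double pr = (1 - fr) * ref_pitch(i0) + fr * ref_pitch(i0 + 1);
      double pdr = (1 - fr) * ref_pitchd(i0) + fr * ref_pitchd(i0 + 1);
      fz_ext = stab_kp_z * (zr - q(1)) + stab_kd_z * (zdr - qd(1));
      my_ext = stab_kp_pitch * (pr - q(2)) + stab_kd_pitch * (pdr - qd(2));
    }

    // belt controller (zero-order hold on the update grid)
    double surf_vx = 0.0;
    if (treadmill_mode == 1) {
      surf_vx = -v_target;
    } else if (treadmill_mode == 2) {
      if (t >= next_update - 1e-12) {
        double a_belt = have_prev ? (belt_v - prev_v_update) / period : 0.0;
        double F = belt_kp * (v_target - belt_v) - belt_kd * a_belt;
        if (F > f_max) F = f_max;
        if (F < -f_max) F = -f_max;
        belt_F = F;
        prev_v_update = belt_v;
        have_prev = true;
        next_update += period;
      }
      surf_vx = -belt_v;
    }

    arma::vec qdd = dynamics_qdd(b, q, qd, tau, fz_ext, my_ext, cp, mu,
                                 0.0, surf_vx, false, contactF, loads);
    if (!qdd.is_finite()) { status = 1; break; }
    qd += dt * qdd;
    q += dt * qd;
    if (!q.is_finite() || !qd.is_finite()) { status = 1; break; }

    // belt dynamics (after body step, using this step's foot loads)
    if (treadmill_mode == 1) {
      belt_pos += v_target * dt;
      belt_v = v_target;
    } else if (treadmill_mode == 2) {
      // loads on the belt along its running axis (-x): tangential foot
      // reaction is -loads[0] in x, i.e. +loads[0] on the belt axis.
      double f_foot = loads[0];
      double n_load = loads[1] > 0.0 ? loads[1] : 0.0;
      double deck = mu_deck * (m_belt * b.g + n_load) * std::tanh(belt_v / veps);
      belt_v += dt * (belt_F + f_foot - deck) / m_belt;
      belt_pos += belt_v * dt;
    }

    log(step, 0) = t + dt;
    for (int i = 0; i < N_Q; ++i) { log(step, 1 + i) = q(i); log(step, 10 + i) = qd(i); }
    for (int i = 0; i < N_CPT; ++i) {
      log(step, 19 + 2 * i) = contactF(i, 0);
      log(step, 20 + 2 * i) = contactF(i, 1);
    }
    log(step, 27) = belt_pos;
    log(step, 28) = belt_v;
    log(step, 29) = belt_F;
    done = step + 1;
  }

  return List::create(_["log"] = log.rows(0, std::max(done - 1, 0)),
                      _["n_done"] = done, _["status"] = status,
                      _["q"] = q, _["qd"] = qd);
}
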