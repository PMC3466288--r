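#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-trial simulation loop of the two-joint six-muscle arm.
//
// Chains, at every time step of a fixed 1 kHz-style grid: reference muscle
// lengths -> RBF feedforward command -> delayed V-shaped feedback ->
// signal-dependent noise -> muscle visco-elastic tensions -> joint torques
// -> environment force -> rigid-body forward dynamics, integrated with
// fixed-step RK4 (activation held within a step).
//
// Field types: 0 = NF, 1 = VF (B matrix; VFk is a per-trial constant B and
// is folded into this case by the caller), 3 = DF with safety barrier.

struct Deriv {
  double qdd1, qdd2;
  double T[6];
  double F[2];
};

static inline void dynamics(const double q[2], const double qd[2],
                            const double u[6],
                            const NumericMatrix &A,
                            const double qr[2], const double qdr[2],
                            double T0, double k0, double k1c, double b0,
                            double b1, double rho,
                            double L1, double L2, double m2d,
                            double Ma, double Mb, double M22c,
                            const double Barm[4],
                            int ftype, const double Bf[4],
                            double df_gain, const double df_start[2],
                            const double df_goal[2], const double df_axis[2],
                            double df_barrier, double df_bdamp,
                            double df_circ,
                            Deriv &out) {
  // stretch and stretch rate relative to the reference trajectory
  // (rest length travels with the descending command, shortened by rho*u)
  double dq1 = q[0] - qr[0], dq2 = q[1] - qr[1];
  double dqd1 = qd[0] - qdr[0], dqd2 = qd[1] - qdr[1];
  double tau1 = 0.0, tau2 = 0.0;
  for (int i = 0; i < 6; ++i) {
    double a1 = A(0, i), a2 = A(1, i);
    double stretch = -(a1 * dq1 + a2 * dq2) + rho * u[i];
    double dldot = -(a1 * dqd1 + a2 * dqd2);
    double T = T0 * u[i] + (k0 + k1c * u[i]) * stretch +
               (b0 + b1 * u[i]) * dldot;
    if (T < 0.0) T = 0.0;
    out.T[i] = T;
    tau1 += a1 * T;
    tau2 += a2 * T;
  }
  // kinematics
  double c2 = std::cos(q[1]), s2 = std::sin(q[1]);
  double s1 = std::sin(q[0]), c1 = std::cos(q[0]);
  double s12 = std::sin(q[0] + q[1]), c12 = std::cos(q[0] + q[1]);
  double J11 = -L1 * s1 - L2 * s12, J12 = -L2 * s12;
  double J21 = L1 * c1 + L2 * c12, J22 = L2 * c12;
  // environment force
  double F1 = 0.0, F2 = 0.0;
  if (ftype != 0) {
    double px = L1 * c1 + L2 * c12, py = L1 * s1 + L2 * s12;
    double vx = J11 * qd[0] + J12 * qd[1];
    double vy = J21 * qd[0] + J22 * qd[1];
    if (ftype == 1) {
      F1 = Bf[0] * vx + Bf[2] * vy;
      F2 = Bf[1] * vx + Bf[3] * vy;
    } else if (ftype == 3) {
      double dsx = px - df_start[0], dsy = py - df_start[1];
      double dgx = px - df_goal[0], dgy = py - df_goal[1];
      bool inside = (dsx * dsx + dsy * dsy <= df_circ * df_circ) ||
                    (dgx * dgx + dgy * dgy <= df_circ * df_circ);
      if (!inside) {
        double nx = -df_axis[1], ny = df_axis[0];  // left normal
        double lat = dsx * nx + dsy * ny;
        if (std::fabs(lat) > df_barrier) {
          double vlat = vx * nx + vy * ny;
          F1 = -df_bdamp * vlat * nx;
          F2 = -df_bdamp * vlat * ny;
        } else {
          F1 = df_gain * lat * nx;
          F2 = df_gain * lat * ny;
        }
      }
    }
  }
  out.F[0] = F1;
  out.F[1] = F2;
  // rigid-body dynamics
  double M11 = Ma + 2.0 * Mb * c2;
  double M12 = M22c + Mb * c2;
  double M22 = M22c;
  double h = m2d * s2;  // m2*L1*lc2*sin(q2)
  double cor1 = -h * qd[1] * qd[0] - h * (qd[0] + qd[1]) * qd[1];
  double cor2 = h * qd[0] * qd[0];
  double r1 = tau1 + J11 * F1 + J21 * F2 - cor1 -
              (Barm[0] * qd[0] + Barm[2] * qd[1]);
  double r2 = tau2 + J12 * F1 + J22 * F2 - cor2 -
              (Barm[1] * qd[0] + Barm[3] * qd[1]);
  double det = M11 * M22 - M12 * M12;
  out.qdd1 = (M22 * r1 - M12 * r2) / det;
  out.qdd2 = (-M12 * r1 + M11 * r2) / det;
}

// arm: L1,L2,m1,m2,lc1,lc2,I1,I2; Barm: 2x2 joint viscosity; A: 2x6 moment
// arms; qref_post: geometry reference posture; musc: T0,k0,k1,b0,b1,rho;
// centers/widths: N x 4 (standardized); W: 6 x N; gains:
// a_plus,a_minus,kappa; df_par: gain,sx,sy,gx,gy,ax,ay,barrier,bdamp,circ_r;
// Z: T x 6 standard normal noise draws.
// [[Rcpp::export(name = ".simulate_trial_cpp")]]
List simulate_trial_cpp(NumericVector arm, NumericMatrix Barm,
                        NumericMatrix A, NumericVector qref_post,
                        NumericVector musc, NumericMatrix centers,
                        NumericMatrix widths,
                        NumericVector sc_center, NumericVector sc_sd,
                        NumericMatrix W, NumericVector gains,
                        int delay_steps,
                        NumericMatrix ref_q, NumericMatrix ref_qd,
                        int ftype, NumericMatrix Bf, NumericVector df_par,
                        double dt, double noise_coef, double noise_alpha,
                        NumericMatrix Z,
                        NumericVector q0, NumericVector qd0,
                        double speed_limit) {
  const int T = ref_q.nrow();
  const int N = centers.nrow();
  const double L1 = arm[0], L2 = arm[1];
  const double m1 = arm[2], m2 = arm[3], lc1 = arm[4], lc2 = arm[5];
  const double I1 = arm[6], I2 = arm[7];
  const double Ma = I1 + I2 + m1 * lc1 * lc1 + m2 * (L1 * L1 + lc2 * lc2);
  const double Mb = m2 * L1 * lc2;
  const double M22c = I2 + m2 * lc2 * lc2;
  const double m2d = Mb;
  double Ba[4] = {Barm(0, 0), Barm(1, 0), Barm(0, 1), Barm(1, 1)};
  double Bff[4] = {0, 0, 0, 0};
  if (ftype == 1) {
    Bff[0] = Bf(0, 0); Bff[1] = Bf(1, 0); Bff[2] = Bf(0, 1); Bff[3] = Bf(1, 1);
  }
  double dfp[2] = {0, 0}, dfg[2] = {0, 0}, dfa[2] = {0, 0};
  double df_gain = 0, df_barrier = 0.05, df_bdamp = 50, df_circ = 0.0125;
  if (ftype == 3) {
    df_gain = df_par[0];
    dfp[0] = df_par[1]; dfp[1] = df_par[2];
    dfg[0] = df_par[3]; dfg[1] = df_par[4];
    dfa[0] = df_par[5]; dfa[1] = df_par[6];
    df_barrier = df_par[7]; df_bdamp = df_par[8]; df_circ = df_par[9];
  }
  const double a_plus = gains[0], a_minus = gains[1], kappa = gains[2];
  const double T0 = musc[0], k0 = musc[1], k1c = musc[2];
  const double b0 = musc[3], b1 = musc[4], rho = musc[5];

  NumericMatrix log_q(T, 2), log_qd(T, 2), log_hand(T, 2), log_hv(T, 2);
  NumericMatrix log_e(T, 6), log_edot(T, 6), log_eps(T, 6);
  NumericMatrix log_uff(T, 6), log_ufb(T, 6), log_u(T, 6), log_T(T, 6);
  NumericMatrix log_F(T, 2), G(T, N);
  bool aborted = false;
  int abort_step = -1;

  double q[2] = {q0[0], q0[1]};
  double qd[2] = {qd0[0], qd0[1]};
  double nstate[6] = {0, 0, 0, 0, 0, 0};
  const double nmix = std::sqrt(1.0 - noise_alpha * noise_alpha);
  Deriv d1, d2, d3, d4;

  for (int t = 0; t < T; ++t) {
    // tracking error in muscle space: e = -A^T (q - q_ref(t))
    double e[6], edot[6];
    for (int i = 0; i < 6; ++i) {
      e[i] = -(A(0, i) * (q[0] - ref_q(t, 0)) + A(1, i) * (q[1] - ref_q(t, 1)));
      edot[i] = -(A(0, i) * (qd[0] - ref_qd(t, 0)) +
                  A(1, i) * (qd[1] - ref_qd(t, 1)));
      log_e(t, i) = e[i];
      log_edot(t, i) = edot[i];
    }
    const double qr_t[2] = {ref_q(t, 0), ref_q(t, 1)};
    const double qdr_t[2] = {ref_qd(t, 0), ref_qd(t, 1)};
    // delayed sliding error and V-shaped feedback
    double u[6], ufb[6], uff[6];
    for (int i = 0; i < 6; ++i) {
      double eps = 0.0;
      if (t >= delay_steps) {
        int td = t - delay_steps;
        eps = log_e(td, i) + kappa * log_edot(td, i);
      }
      log_eps(t, i) = eps;
      ufb[i] = (eps > 0.0) ? a_plus * eps : -a_minus * eps;
    }
    // RBF feedforward
    double x[4] = {q[0], q[1], qd[0], qd[1]};
    double z[4];
    for (int d = 0; d < 4; ++d) z[d] = (x[d] - sc_center[d]) / sc_sd[d];
    for (int i = 0; i < 6; ++i) uff[i] = 0.0;
    for (int j = 0; j < N; ++j) {
      double s = 0.0;
      for (int d = 0; d < 4; ++d) {
        double r = (z[d] - centers(j, d)) / widths(j, d);
        s += r * r;
      }
      double g = std::exp(-0.5 * s);
      G(t, j) = g;
      for (int i = 0; i < 6; ++i) uff[i] += W(i, j) * g;
    }
    for (int i = 0; i < 6; ++i) {
      if (uff[i] < 0.0) uff[i] = 0.0;
      log_uff(t, i) = uff[i];
      log_ufb(t, i) = ufb[i];
      double udes = uff[i] + ufb[i];
      nstate[i] = noise_alpha * nstate[i] +
                  nmix * noise_coef * udes * Z(t, i);
      u[i] = udes + nstate[i];
      if (u[i] < 0.0) u[i] = 0.0;
      log_u(t, i) = u[i];
    }
    // RK4 step with activation held
    dynamics(q, qd, u, A, qr_t, qdr_t, T0, k0, k1c, b0, b1, rho, L1, L2, m2d,
             Ma, Mb, M22c, Ba, ftype, Bff, df_gain, dfp, dfg, dfa,
             df_barrier, df_bdamp, df_circ, d1);
    for (int i = 0; i < 6; ++i) log_T(t, i) = d1.T[i];
    log_F(t, 0) = d1.F[0]; log_F(t, 1) = d1.F[1];
    {
      double s1v = std::sin(q[0]), c1v = std::cos(q[0]);
      double s12v = std::sin(q[0] + q[1]), c12v = std::cos(q[0] + q[1]);
      log_hand(t, 0) = L1 * c1v + L2 * c12v;
      log_hand(t, 1) = L1 * s1v + L2 * s12v;
      double J11 = -L1 * s1v - L2 * s12v, J12 = -L2 * s12v;
      double J21 = L1 * c1v + L2 * c12v, J22 = L2 * c12v;
      log_hv(t, 0) = J11 * qd[0] + J12 * qd[1];
      log_hv(t, 1) = J21 * qd[0] + J22 * qd[1];
      double sp = std::sqrt(log_hv(t, 0) * log_hv(t, 0) +
                            log_hv(t, 1) * log_hv(t, 1));
      if (!std::isfinite(sp) || sp > speed_limit) {
        aborted = true;
        abort_step = t + 1;
      }
    }
    log_q(t, 0) = q[0]; log_q(t, 1) = q[1];
    log_qd(t, 0) = qd[0]; log_qd(t, 1) = qd[1];
    if (aborted) break;
    if (t == T - 1) break;

    double qa[2], qda[2];
    // k2
    qa[0] = q[0] + 0.5 * dt * qd[0]; qa[1] = q[1] + 0.5 * dt * qd[1];
    qda[0] = qd[0] + 0.5 * dt * d1.qdd1; qda[1] = qd[1] + 0.5 * dt * d1.qdd2;
    dynamics(qa, qda, u, A, qr_t, qdr_t, T0, k0, k1c, b0, b1, rho, L1, L2, m2d,
             Ma, Mb, M22c, Ba, ftype, Bff, df_gain, dfp, dfg, dfa,
             df_barrier, df_bdamp, df_circ, d2);
    double k2q[2] = {qda[0], qda[1]};
    // k3
    qa[0] = q[0] + 0.5 * dt * k2q[0]; qa[1] = q[1] + 0.5 * dt * k2q[1];
    qda[0] = qd[0] + 0.5 * dt * d2.qdd1; qda[1] = qd[1] + 0.5 * dt * d2.qdd2;
    dynamics(qa, qda, u, A, qr_t, qdr_t, T0, k0, k1c, b0, b1, rho, L1, L2, m2d,
             Ma, Mb, M22c, Ba, ftype, Bff, df_gain, dfp, dfg, dfa,
             df_barrier, df_bdamp, df_circ, d3);
    double k3q[2] = {qda[0], qda[1]};
    // k4
    qa[0] = q[0] + dt * k3q[0]; qa[1] = q[1] + dt * k3q[1];
    qda[0] = qd[0] + dt * d3.qdd1; qda[1] = qd[1] + dt * d3.qdd2;
    dynamics(qa, qda, u, A, qr_t, qdr_t, T0, k0, k1c, b0, b1, rho, L1, L2, m2d,
             Ma, Mb, M22c, Ba, ftype, Bff, df_gain, dfp, dfg, dfa,
             df_barrier, df_bdamp, df_circ, d4);
    double k4q[2] = {qda[0], qda[1]};

    q[0] += dt / 6.0 * (qd[0] + 2.0 * k2q[0] + 2.0 * k3q[0] + k4q[0]);
    q[1] += dt / 6.0 * (qd[1] + 2.0 * k2q[1] + 2.0 * k3q[1] + k4q[1]);
    qd[0] += dt / 6.0 * (d1.qdd1 + 2.0 * d2.qdd1 + 2.0 * d3.qdd1 + d4.qdd1);
    qd[1] += dt / 6.0 * (d1.qdd2 + 2.0 * d2.qdd2 + 2.0 * d3.qdd2 + d4.qdd2);
  }

  return List::create(
      _["q"] = log_q, _["qdot"] = log_qd, _["hand"] = log_hand,
      _["hand_vel"] = log_hv, _["e"] = log_e, _["edot"] = log_edot,
      _["eps"] = log_eps, _["u_ff"] = log_uff, _["u_fb"] = log_ufb,
      _["u"] = log_u, _["tension"] = log_T, _["F_ext"] = log_F,
      _["G"] = G, _["aborted"] = aborted, _["abort_step"] = abort_step);
}
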