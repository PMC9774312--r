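#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Compressible orifice flow function f1(r): 1 on the choked branch
// (r <= r_crit), (eta1/eta2) sqrt(r^(2/k) - r^((k+1)/k)) subsonic.
static inline double f1_flow(double r, double k, double eta1, double eta2,
                             double r_crit) {
  if (r <= r_crit) return 1.0;
  if (r >= 1.0) return 0.0;
  double a = std::pow(r, 2.0 / k) - std::pow(r, (k + 1.0) / k);
  if (a < 0) a = 0;
  return eta1 / eta2 * std::sqrt(a);
}

// positive remainder of t modulo period
static inline double phase_mod(double t, double period) {
  double r = t - std::floor(t / period) * period;
  return r < 0 ? r + period : r;
}

struct ActParams {
  // gas
  double Rg, k, c0, eta1, eta2, r_crit;
  // regulator
  double tau_v, k_v, w;
  // cylinder
  double A1, A2, L, X10, X20, MW, F1, F3, Ps, Ts, Pa, Ta, A_exh1, A_exh2;
  // chest
  double k1, m_damp;
};

// dy for state y = {xv, P1, P2, X, Xdot}; comp = compression phase
// (chamber 1 charging from supply, chamber 2 exhausting); u is the
// regulator command voltage held over the step.
static void act_rhs(const double *y, double *dy, bool comp, double u,
                    const ActParams &p) {
  double xv = y[0] > 0 ? y[0] : 0;
  double P1 = y[1], P2 = y[2], X = y[3], Xdot = y[4];
  if (X < 0) X = 0;
  if (X > p.L) X = p.L;

  dy[0] = (p.k_v * u - y[0]) / p.tau_v;

  double A0 = xv * p.w;
  double sQRT_s = std::sqrt(p.Rg * p.Ts);
  double sQRT_a = std::sqrt(p.Rg * p.Ta);

  // charging chamber: supply -> chamber through regulator throttle
  // discharging chamber: chamber -> ambient through valve exhaust port
  // (reverse flow from ambient allowed if the chamber falls below Pa)
  double Qin1 = 0, Tin1 = p.Ts, Qout1 = 0;
  double Qin2 = 0, Tin2 = p.Ts, Qout2 = 0;

  double ex = (p.k - 1.0) / p.k;
  double T1c = p.Ts * std::pow(P1 / p.Ps, ex);  // isentropic chamber temp
  double T2c = p.Ts * std::pow(P2 / p.Ps, ex);

  if (comp) {
    if (P1 < p.Ps)
      Qin1 = p.c0 * p.eta2 * A0 * p.Ps / sQRT_s *
             f1_flow(P1 / p.Ps, p.k, p.eta1, p.eta2, p.r_crit);
    if (P2 > p.Pa)
      Qout2 = p.c0 * p.eta2 * p.A_exh2 * P2 / std::sqrt(p.Rg * T2c) *
              f1_flow(p.Pa / P2, p.k, p.eta1, p.eta2, p.r_crit);
    else if (P2 < p.Pa) {
      Qin2 = p.c0 * p.eta2 * p.A_exh2 * p.Pa / sQRT_a *
             f1_flow(P2 / p.Pa, p.k, p.eta1, p.eta2, p.r_crit);
      Tin2 = p.Ta;
    }
  } else {
    if (P2 < p.Ps)
      Qin2 = p.c0 * p.eta2 * A0 * p.Ps / sQRT_s *
             f1_flow(P2 / p.Ps, p.k, p.eta1, p.eta2, p.r_crit);
    if (P1 > p.Pa)
      Qout1 = p.c0 * p.eta2 * p.A_exh1 * P1 / std::sqrt(p.Rg * T1c) *
              f1_flow(p.Pa / P1, p.k, p.eta1, p.eta2, p.r_crit);
    else if (P1 < p.Pa) {
      Qin1 = p.c0 * p.eta2 * p.A_exh1 * p.Pa / sQRT_a *
             f1_flow(P1 / p.Pa, p.k, p.eta1, p.eta2, p.r_crit);
      Tin1 = p.Ta;
    }
  }

  double V1 = p.A1 * (p.X10 + X);
  double V2 = p.A2 * (p.L + p.X20 - X);
  dy[1] = (p.k * p.Rg * (Tin1 * Qin1 - T1c * Qout1) -
           p.k * P1 * p.A1 * Xdot) / V1;
  dy[2] = (p.k * p.Rg * (Tin2 * Qin2 - T2c * Qout2) +
           p.k * P2 * p.A2 * Xdot) / V2;

  // piston force balance; a0 derates the working area at breakaway
  double a0 = (X <= 0) ? 0.8 : 1.0;
  double F2 = p.k1 * (X > 0 ? X : 0) + p.m_damp * Xdot;
  double load = F2 - p.F3 + p.Pa * (p.A1 - p.A2);
  double thrust = a0 * P1 * p.A1 - P2 * p.A2 - load;
  double acc;
  const double vtol = 1e-9;
  if (std::fabs(Xdot) > vtol) {
    acc = (thrust - (Xdot > 0 ? p.F1 : -p.F1)) / p.MW;
  } else {
    if (std::fabs(thrust) <= p.F1) acc = 0;
    else acc = (thrust - (thrust > 0 ? p.F1 : -p.F1)) / p.MW;
  }
  dy[3] = Xdot;
  dy[4] = acc;
}

// [[Rcpp::export]]
List sim_actuator_cpp(List gas, List reg, List cyl, List chest, List pid,
                      double depth_m, double period, double duty,
                      int n_cycles, double dt, int sample_every) {
  ActParams p;
  p.Rg = gas["R"]; p.k = gas["k"]; p.c0 = gas["c0"];
  p.eta1 = gas["eta1"]; p.eta2 = gas["eta2"]; p.r_crit = gas["r_crit"];
  p.tau_v = reg["tau_v"]; p.k_v = reg["k_v"]; p.w = reg["w"];
  p.A1 = cyl["A1"]; p.A2 = cyl["A2"]; p.L = cyl["L"];
  p.X10 = cyl["X10"]; p.X20 = cyl["X20"]; p.MW = cyl["M_W"];
  p.F1 = cyl["F1"]; p.F3 = cyl["F3"]; p.Ps = cyl["Ps"]; p.Ts = cyl["Ts"];
  p.Pa = cyl["Pa"]; p.Ta = cyl["Ta"];
  p.A_exh1 = cyl["A_exh1"]; p.A_exh2 = cyl["A_exh2"];
  p.k1 = chest["k1"]; p.m_damp = chest["m"];
  double kp = pid["kp"], ki = pid["ki"], kd = pid["kd"],
         umax = pid["u_max"];

  int n_steps = (int)std::round(n_cycles * period / dt);
  int n_rec = n_steps / sample_every + 1;
  NumericVector rt(n_rec), rX(n_rec), rV(n_rec), rP1(n_rec), rP2(n_rec),
                rxv(n_rec), ru(n_rec);

  double y[5] = {0.0, p.Pa, p.Pa, 0.0, 0.0};
  double integral = 0, prev_e = 0;
  bool prev_comp = false;
  int irec = 0;
  double u = 0;
  double t_on = duty * period;

  for (int i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    double phase = phase_mod(t, period);
    bool comp = phase < t_on && i < n_steps;

    // controller: PID tracks the commanded depth during compression; the
    // regulator is driven wide open during decompression (full-speed
    // retraction through the commuted valve)
    if (comp) {
      double e = depth_m - y[3];
      if (!prev_comp) prev_e = e;  // avoid derivative kick at the edge
      double deriv = (e - prev_e) / dt;
      double int_trial = integral + e * dt;
      double u_raw = kp * e + ki * int_trial + kd * deriv;
      u = u_raw > umax ? umax : (u_raw < 0 ? 0 : u_raw);
      if (!((u_raw > umax && e > 0) || (u_raw < 0 && e < 0)))
        integral = int_trial;
      prev_e = e;
    } else {
      u = umax;
    }
    prev_comp = comp;

    if (i % sample_every == 0 && irec < n_rec) {
      rt[irec] = t; rxv[irec] = y[0]; rP1[irec] = y[1]; rP2[irec] = y[2];
      rX[irec] = y[3]; rV[irec] = y[4]; ru[irec] = u;
      ++irec;
    }
    if (i == n_steps) break;

    // classical RK4 step
    double k1v[5], k2v[5], k3v[5], k4v[5], ytmp[5];
    act_rhs(y, k1v, comp, u, p);
    for (int j = 0; j < 5; ++j) ytmp[j] = y[j] + 0.5 * dt * k1v[j];
    act_rhs(ytmp, k2v, comp, u, p);
    for (int j = 0; j < 5; ++j) ytmp[j] = y[j] + 0.5 * dt * k2v[j];
    act_rhs(ytmp, k3v, comp, u, p);
    for (int j = 0; j < 5; ++j) ytmp[j] = y[j] + dt * k3v[j];
    act_rhs(ytmp, k4v, comp, u, p);
    for (int j = 0; j < 5; ++j)
      y[j] += dt / 6.0 * (k1v[j] + 2 * k2v[j] + 2 * k3v[j] + k4v[j]);

    // inelastic stroke stops
    if (y[3] <= 0) { y[3] = 0; if (y[4] < 0) y[4] = 0; }
    if (y[3] >= p.L) { y[3] = p.L; if (y[4] > 0) y[4] = 0; }
    if (y[0] < 0) y[0] = 0;
    if (y[1] < 1.0) y[1] = 1.0;
    if (y[2] < 1.0) y[2] = 1.0;
    if (!std::isfinite(y[1]) || !std::isfinite(y[2]) ||
        !std::isfinite(y[4]))
      stop("actuator integration diverged at t = %f s "
           "(reduce dt or check parameters)", t);
  }

  return List::create(_["t"] = rt, _["X"] = rX, _["Xdot"] = rV,
                      _["P1"] = rP1, _["P2"] = rP2, _["xv"] = rxv,
                      _["u"] = ru);
}
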