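#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lumped-parameter circulation: compartment stored (transmural) pressures
// x_i with compliances C_i [mL/mmHg]; resistive edges Q_e = dP/R_e
// [mL/s, R in mmHg s/mL], ideal-diode valves; external pressure sources
// P_M (mediastinal, applied to intrathoracic compartments) and P_lung
// (alveolar, applied to the pulmonary vascular compartment) driven by the
// chest velocity. Fixed-step RK4.
struct CircNet {
  int nc, ne;
  std::vector<double> C;
  std::vector<int> thor, pulm, efrom, eto, valve;
  std::vector<double> R;
  // sources
  double E_over_d0;   // mmHg per m of chest travel
  double A_L;         // m^2
  double R_airway;    // mmHg s/L
  double C_lung;      // L/mmHg
  double P_mouth;     // mmHg
  bool x2_volume;     // couple vessel-expansion speed to thoracic volume
  double A_eff;       // m^2, effective area for the x2 coupling
};

// state vector: x[0..nc-1], PM, Plung
static void circ_rhs(const std::vector<double> &s, std::vector<double> &ds,
                     double Xdot, const CircNet &n,
                     std::vector<double> &Peff, std::vector<double> &Q) {
  double PM = s[n.nc], Plung = s[n.nc + 1];
  for (int i = 0; i < n.nc; ++i)
    Peff[i] = s[i] + (n.thor[i] ? PM : 0.0) + (n.pulm[i] ? Plung : 0.0);
  for (int i = 0; i < n.nc; ++i) ds[i] = 0;
  for (int e = 0; e < n.ne; ++e) {
    double q = (Peff[n.efrom[e]] - Peff[n.eto[e]]) / n.R[e];
    if (n.valve[e] && q < 0) q = 0;
    Q[e] = q;
    ds[n.efrom[e]] -= q;
    ds[n.eto[e]] += q;
  }
  double dVthor = 0;  // mL/s of intrathoracic vascular volume change
  for (int i = 0; i < n.nc; ++i) {
    ds[i] /= n.C[i];
    if (n.thor[i]) dVthor += n.C[i] * ds[i];
  }
  double x2dot = n.x2_volume ? dVthor * 1e-6 / n.A_eff : 0.0;  // m/s
  ds[n.nc] = n.E_over_d0 * (Xdot + x2dot);
  // Xdot A_L in m^3/s -> *1000 L/s; airway leak (Plung - Pmouth)/Rairway
  ds[n.nc + 1] = (Xdot * n.A_L * 1000.0 -
                  (Plung - n.P_mouth) / n.R_airway) / n.C_lung;
}

// [[Rcpp::export]]
List sim_circulation_cpp(NumericVector C, IntegerVector thor,
                         IntegerVector pulm, NumericVector x0,
                         IntegerVector efrom, IntegerVector eto,
                         NumericVector Redge, IntegerVector valve,
                         NumericVector drive_xdot, double drive_dt,
                         double period, List sources, int n_cycles,
                         int warmup_cycles, double dt, int sample_every) {
  CircNet n;
  n.nc = C.size(); n.ne = Redge.size();
  n.C = as<std::vector<double>>(C);
  n.thor = as<std::vector<int>>(thor);
  n.pulm = as<std::vector<int>>(pulm);
  n.efrom = as<std::vector<int>>(efrom);
  n.eto = as<std::vector<int>>(eto);
  n.valve = as<std::vector<int>>(valve);
  n.R = as<std::vector<double>>(Redge);
  n.E_over_d0 = sources["E_over_d0"];
  n.A_L = sources["A_L"];
  n.R_airway = sources["R_airway"];
  n.C_lung = sources["C_lung"];
  n.P_mouth = sources["P_mouth"];
  n.x2_volume = as<bool>(sources["x2_volume"]);
  n.A_eff = sources["A_eff"];

  int nd = drive_xdot.size();
  auto xdot_at = [&](double t) -> double {
    double phase = t - std::floor(t / period) * period;
    double fi = phase / drive_dt;
    int i0 = (int)std::floor(fi);
    double w = fi - i0;
    int i1 = i0 + 1;
    if (i0 >= nd) i0 = nd - 1;
    if (i1 >= nd) i1 = nd - 1;
    return drive_xdot[i0] * (1 - w) + drive_xdot[i1] * w;
  };

  int steps_per_cycle = (int)std::round(period / dt);
  int n_steps = n_cycles * steps_per_cycle;
  int rec_start = warmup_cycles * steps_per_cycle;
  int n_rec = (n_steps - rec_start) / sample_every + 1;

  NumericVector rt(n_rec), rPM(n_rec), rPl(n_rec);
  NumericMatrix rP(n_rec, n.nc), rQ(n_rec, n.ne), rX(n_rec, n.nc);

  int dim = n.nc + 2;
  std::vector<double> s(dim), k1(dim), k2(dim), k3(dim), k4(dim),
      tmp(dim), Peff(n.nc), Q(n.ne);
  for (int i = 0; i < n.nc; ++i) s[i] = x0[i];
  s[n.nc] = 0.0;          // P_M
  s[n.nc + 1] = n.P_mouth;  // P_lung

  int irec = 0;
  for (int i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    if (i >= rec_start && (i - rec_start) % sample_every == 0 &&
        irec < n_rec) {
      circ_rhs(s, k1, xdot_at(t), n, Peff, Q);  // refresh Peff, Q
      rt[irec] = t; rPM[irec] = s[n.nc]; rPl[irec] = s[n.nc + 1];
      for (int c = 0; c < n.nc; ++c) {
        rP(irec, c) = Peff[c];
        rX(irec, c) = s[c];
      }
      for (int e = 0; e < n.ne; ++e) rQ(irec, e) = Q[e];
      ++irec;
    }
    if (i == n_steps) break;

    circ_rhs(s, k1, xdot_at(t), n, Peff, Q);
    for (int j = 0; j < dim; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    circ_rhs(tmp, k2, xdot_at(t + 0.5 * dt), n, Peff, Q);
    for (int j = 0; j < dim; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    circ_rhs(tmp, k3, xdot_at(t + 0.5 * dt), n, Peff, Q);
    for (int j = 0; j < dim; ++j) tmp[j] = s[j] + dt * k3[j];
    circ_rhs(tmp, k4, xdot_at(t + dt), n, Peff, Q);
    for (int j = 0; j < dim; ++j)
      s[j] += dt / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);

    if (!std::isfinite(s[0]) || !std::isfinite(s[n.nc]))
      stop("circulation integration diverged at t = %f s", t);
  }

  return List::create(_["t"] = rt, _["P"] = rP, _["x"] = rX, _["Q"] = rQ,
                      _["PM"] = rPM, _["Plung"] = rPl);
}
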