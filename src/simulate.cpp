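// Fixed-step RK4 integrator for the virtual-patient glucose-insulin model.
//
// State vector (14 compartments):
//   0 Qsto1  gastric glucose, first compartment (mg)
//   1 Qsto2  gastric glucose, second compartment (mg)
//   2 Qgut   intestinal glucose (mg)
//   3 Gp     plasma glucose mass (mg/kg)
//   4 Gt     tissue glucose mass (mg/kg)
//   5 Ip     plasma insulin (pmol/kg)
//   6 Il     liver insulin (pmol/kg)
//   7 Ipo    portal (pre-hepatic) insulin (pmol/kg)
//   8 I1     delayed insulin signal, stage 1 (pmol/L)
//   9 Id     delayed insulin signal acting on EGP (pmol/L)
//  10 X      remote insulin action on utilization (pmol/L, deviation)
//  11 Y      beta-cell response to glucose level (pmol/kg/min, deviation)
//  12 Isc1   subcutaneous insulin depot 1 (pmol/kg)
//  13 Isc2   subcutaneous insulin depot 2 (pmol/kg)
//
// X and Y are deviation variables and may legitimately be negative; all
// other compartments are clamped at zero after every step with the clamp
// magnitude tracked.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Params {
  double VG, k1, k2, VI, m1, m2, m3, m4;
  double kmax, kmin, kabs, kgri, b, d, f;
  double kp2, ki, Fcns, Km0, p2U, alpha, gamma_, ke1, ke2;
  double kd, ka1, ka2, pmol_per_U;
  double kp1, Vm0, Sb;          // basal-state derived
  double Vmx, Kresp, beta, kp3; // patient severity
  double Gb, Ib, BW;
};

static Params unpack(const NumericVector& p) {
  Params P;
  P.VG = p["VG"]; P.k1 = p["k1"]; P.k2 = p["k2"];
  P.VI = p["VI"]; P.m1 = p["m1"]; P.m2 = p["m2"]; P.m3 = p["m3"]; P.m4 = p["m4"];
  P.kmax = p["kmax"]; P.kmin = p["kmin"]; P.kabs = p["kabs"]; P.kgri = p["kgri"];
  P.b = p["b"]; P.d = p["d"]; P.f = p["f"];
  P.kp2 = p["kp2"]; P.ki = p["ki"]; P.Fcns = p["Fcns"]; P.Km0 = p["Km0"];
  P.p2U = p["p2U"]; P.alpha = p["alpha"]; P.gamma_ = p["gamma"];
  P.ke1 = p["ke1"]; P.ke2 = p["ke2"];
  P.kd = p["kd"]; P.ka1 = p["ka1"]; P.ka2 = p["ka2"];
  P.pmol_per_U = p["pmol_per_U"];
  P.kp1 = p["kp1"]; P.Vm0 = p["Vm0"]; P.Sb = p["Sb"];
  P.Vmx = p["Vmx"]; P.Kresp = p["Kresp"]; P.beta = p["beta"]; P.kp3 = p["kp3"];
  P.Gb = p["Gb"]; P.Ib = p["Ib"]; P.BW = p["BW"];
  return P;
}

// Exogenous forcings at time t, all piecewise constant.
// meals: columns (start_min, mass_mg, duration_min), already replicated over
// the simulated days. boluses: columns (time_min, dose_U).
struct Events {
  std::vector<double> meal_start, meal_mass, meal_dur;
  std::vector<double> bolus_time, bolus_dose;
  double basal_U_per_h;
};

static void forcings(double t, const Events& ev, double pmol_per_U, double BW,
                     double* meal_mg_min, double* Dmeal_mg, double* iir) {
  double rate = 0.0, D = 0.0, last_start = -1e18;
  for (size_t i = 0; i < ev.meal_start.size(); ++i) {
    const double s = ev.meal_start[i];
    if (t >= s && t < s + ev.meal_dur[i]) rate += ev.meal_mass[i] / ev.meal_dur[i];
    if (s <= t) {
      if (s > last_start) { last_start = s; D = ev.meal_mass[i]; }
      else if (s == last_start) D += ev.meal_mass[i];
    }
  }
  double u = ev.basal_U_per_h / 60.0;
  for (size_t i = 0; i < ev.bolus_time.size(); ++i) {
    const double tb = ev.bolus_time[i];
    if (t >= tb && t < tb + 1.0) u += ev.bolus_dose[i]; // 1-min pulse, U/min
  }
  *meal_mg_min = rate;
  *Dmeal_mg = D;
  *iir = u * pmol_per_U / BW; // pmol/kg/min
}

static void rhs(const double* y, double* dy, const Params& P,
                double meal_mg_min, double Dmeal, double iir) {
  const double Qsto1 = y[0], Qsto2 = y[1], Qgut = y[2], Gp = y[3], Gt = y[4],
               Ip = y[5], Il = y[6], Ipo = y[7], I1 = y[8], Id = y[9],
               X = y[10], Y = y[11], Isc1 = y[12], Isc2 = y[13];
  const double G = Gp / P.VG;
  const double I = Ip / P.VI;

  // gastric emptying: nonlinear in total stomach content relative to the
  // size D of the most recent meal (kmax when the stomach is nearly full or
  // nearly empty, kmin in between)
  double kempt = P.kmax;
  const double Qsto = Qsto1 + Qsto2;
  if (Dmeal > 0.0) {
    const double aa = 5.0 / (2.0 * Dmeal * (1.0 - P.b));
    const double cc = 5.0 / (2.0 * Dmeal * P.d);
    kempt = P.kmin + (P.kmax - P.kmin) / 2.0 *
            (std::tanh(aa * (Qsto - P.b * Dmeal)) -
             std::tanh(cc * (Qsto - P.d * Dmeal)) + 2.0);
  }
  dy[0] = -P.kgri * Qsto1 + meal_mg_min;
  dy[1] = P.kgri * Qsto1 - kempt * Qsto2;
  dy[2] = kempt * Qsto2 - P.kabs * Qgut;
  const double Ra = P.f * P.kabs * Qgut / P.BW; // mg/kg/min

  double EGP = P.kp1 - P.kp2 * Gp - P.kp3 * Id;
  if (EGP < 0.0) EGP = 0.0;
  const double E = (Gp > P.ke2) ? P.ke1 * (Gp - P.ke2) : 0.0;
  double Vmt = P.Vm0 + P.Vmx * X;
  if (Vmt < 0.0) Vmt = 0.0;
  const double Uid = Vmt * Gt / (P.Km0 + Gt);

  dy[3] = EGP + Ra - P.Fcns - E - P.k1 * Gp + P.k2 * Gt;
  dy[4] = -Uid + P.k1 * Gp - P.k2 * Gt;
  const double dG = dy[3] / P.VG;

  // secretion: static response to glucose above basal (via Y) plus dynamic
  // response to rising glucose; beta and Kresp are whole-body
  // responsivities, normalized by body mass
  double Ytarget = P.beta / P.BW * (G - P.Gb);
  if (Ytarget < -P.Sb) Ytarget = -P.Sb;
  dy[11] = -P.alpha * (Y - Ytarget);
  double Spo = Y + P.Sb + ((dG > 0.0) ? P.Kresp / P.BW * dG : 0.0);
  if (Spo < 0.0) Spo = 0.0;
  dy[7] = -P.gamma_ * Ipo + Spo;
  const double S = P.gamma_ * Ipo;

  const double Rai = P.ka1 * Isc1 + P.ka2 * Isc2;
  dy[6] = -(P.m1 + P.m3) * Il + P.m2 * Ip + S;
  dy[5] = -(P.m2 + P.m4) * Ip + P.m1 * Il + Rai;
  dy[8] = -P.ki * (I1 - I);
  dy[9] = -P.ki * (Id - I1);
  dy[10] = -P.p2U * X + P.p2U * (I - P.Ib);
  dy[12] = -(P.kd + P.ka1) * Isc1 + iir;
  dy[13] = P.kd * Isc1 - P.ka2 * Isc2;
}

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericVector params, NumericVector state0,
                  NumericMatrix meals, NumericMatrix boluses,
                  double basal_U_per_h, double t_end, double dt) {
  const Params P = unpack(params);
  const int ns = 14;
  if (state0.size() != ns) stop("state0 must have 14 components");
  const int nt = (int)std::lround(t_end / dt) + 1;

  Events ev;
  ev.basal_U_per_h = basal_U_per_h;
  for (int i = 0; i < meals.nrow(); ++i) {
    ev.meal_start.push_back(meals(i, 0));
    ev.meal_mass.push_back(meals(i, 1));
    ev.meal_dur.push_back(meals(i, 2));
  }
  for (int i = 0; i < boluses.nrow(); ++i) {
    ev.bolus_time.push_back(boluses(i, 0));
    ev.bolus_dose.push_back(boluses(i, 1));
  }

  // forcings are piecewise constant; tabulate them once on the step grid
  // and the half-step grid instead of scanning the event lists per stage
  std::vector<double> mr_lo(nt), Dm_lo(nt), ii_lo(nt);
  std::vector<double> mr_mid(nt), Dm_mid(nt), ii_mid(nt);
  for (int it = 0; it < nt; ++it) {
    const double t = it * dt;
    forcings(t, ev, P.pmol_per_U, P.BW, &mr_lo[it], &Dm_lo[it], &ii_lo[it]);
    forcings(t + 0.5 * dt, ev, P.pmol_per_U, P.BW,
             &mr_mid[it], &Dm_mid[it], &ii_mid[it]);
  }

  std::vector<double> y(state0.begin(), state0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  NumericVector time(nt), G(nt), I(nt);
  double max_clamp = 0.0;
  bool ok = true;

  // X (10) and Y (11) are deviations and exempt from the non-negativity clamp
  static const bool clamped[14] = {true, true, true, true, true, true, true,
                                   true, true, true, false, false, true, true};

  time[0] = 0.0;
  G[0] = y[3] / P.VG;
  I[0] = y[5] / P.VI;

  for (int it = 1; it < nt; ++it) {
    const int i0 = it - 1;

    rhs(y.data(), k1.data(), P, mr_lo[i0], Dm_lo[i0], ii_lo[i0]);
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];

    rhs(tmp.data(), k2.data(), P, mr_mid[i0], Dm_mid[i0], ii_mid[i0]);
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    rhs(tmp.data(), k3.data(), P, mr_mid[i0], Dm_mid[i0], ii_mid[i0]);
    for (int j = 0; j < ns; ++j) tmp[j] = y[j] + dt * k3[j];

    rhs(tmp.data(), k4.data(), P, mr_lo[it], Dm_lo[it], ii_lo[it]);

    for (int j = 0; j < ns; ++j) {
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (clamped[j] && y[j] < 0.0) {
        if (-y[j] > max_clamp) max_clamp = -y[j];
        y[j] = 0.0;
      }
      if (!std::isfinite(y[j])) ok = false;
    }
    if (!ok) break;
    time[it] = it * dt;
    G[it] = y[3] / P.VG;
    I[it] = y[5] / P.VI;
  }

  return List::create(_["time"] = time, _["glucose"] = G, _["insulin"] = I,
                      _["state_end"] = NumericVector(y.begin(), y.end()),
                      _["max_clamp"] = max_clamp, _["ok"] = ok);
}
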