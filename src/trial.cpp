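// Four-action-channel cortico-basal-ganglia-thalamic network integrator.
//
// Regions (4 channels each unless noted): C cortex, G striatum-Go,
// N striatum-NoGo, E globus pallidus externa, I globus pallidus interna,
// T thalamus; one diffuse subthalamic (STN) unit.  Each unit is a
// first-order leaky integrator with a sigmoidal output in [0, 1]:
//   tau du/dt = -u + input,  y = 1 / (1 + exp(-a (u - c))).
// Wiring: cortex -> STN -> GPi (hyperdirect, diffuse); Go -| GPi (direct);
// NoGo -| GPe -| {GPi, STN} (indirect); GPi -| thalamus -> cortex;
// cortical self-excitation + lateral inhibition (winner-takes-all).
// Go is potentiated by D1 occupancy, NoGo depressed by D2 occupancy, both
// scaled by a constant cholinergic factor.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sig(double u, double a, double c) {
  return 1.0 / (1.0 + std::exp(-a * (u - c)));
}

struct NetP {
  double dt;
  double tauC, tauG, tauN, tauE, tauI, tauT, tauS;
  double aC, aG, aN, aE, aI, aT, aS;
  double cC, cG, cN, cE, cI, cT, cS;
  double wCC, wCL, wCT, wTC, wTI, bT;
  double wEN, bE, wIG, wIE, wIS, bI, wSC, wSE, bS;
  double wNG;  // NoGo -> Go collateral inhibition within the striatum
  double kS, kC;  // structural gains on stimulus-> and cortex->striatum paths
  double kD1, kD2, chi, noise;
};

static NetP unpack(const List& np, double dt) {
  NetP p;
  p.dt = dt;
  p.tauC = np["tau_cortex"];   p.tauG = np["tau_go"];
  p.tauN = np["tau_nogo"];     p.tauE = np["tau_gpe"];
  p.tauI = np["tau_gpi"];      p.tauT = np["tau_thal"];
  p.tauS = np["tau_stn"];
  p.aC = np["slope_cortex"];   p.cC = np["center_cortex"];
  p.aG = np["slope_striatum"]; p.cG = np["center_go"];
  p.aN = np["slope_striatum"]; p.cN = np["center_nogo"];
  p.aE = np["slope_gpe"];      p.cE = np["center_gpe"];
  p.aI = np["slope_gpi"];      p.cI = np["center_gpi"];
  p.aT = np["slope_thal"];     p.cT = np["center_thal"];
  p.aS = np["slope_stn"];      p.cS = np["center_stn"];
  p.wCC = np["w_cortex_self"]; p.wCL = np["w_cortex_lateral"];
  p.wCT = np["w_thal_cortex"]; p.wTC = np["w_cortex_thal"];
  p.wTI = np["w_gpi_thal"];    p.bT  = np["drive_thal"];
  p.wEN = np["w_nogo_gpe"];    p.bE  = np["drive_gpe"];
  p.wIG = np["w_go_gpi"];      p.wIE = np["w_gpe_gpi"];
  p.wIS = np["w_stn_gpi"];     p.bI  = np["drive_gpi"];
  p.wSC = np["w_cortex_stn"];  p.wSE = np["w_gpe_stn"];
  p.bS  = np["drive_stn"];
  p.wNG = np["w_nogo_go"];
  p.kS  = np["w_stim_striatum"];
  p.kC  = np["w_cortex_striatum"];
  p.kD1 = np["gain_d1"];       p.kD2 = np["gain_d2"];
  p.chi = np["chi"];           p.noise = np["noise_amp"];
  return p;
}

struct NetState {
  double uC[4], uG[4], uN[4], uE[4], uI[4], uT[4], uS;
};

// One Euler step.  S: stimulus vector; D1/D2: instantaneous occupancies;
// noise: per-channel cortical input noise (already drawn).
static void net_step(NetState& s, const NetP& p, const double* S,
                     const NumericMatrix& wGS, const NumericMatrix& wNS,
                     const NumericVector& wGC, const NumericVector& wNC,
                     double D1, double D2, const double* noise) {
  double yC[4], yG[4], yN[4], yE[4], yI[4], yT[4];
  for (int j = 0; j < 4; ++j) {
    yC[j] = sig(s.uC[j], p.aC, p.cC);
    yG[j] = sig(s.uG[j], p.aG, p.cG);
    yN[j] = sig(s.uN[j], p.aN, p.cN);
    yE[j] = sig(s.uE[j], p.aE, p.cE);
    yI[j] = sig(s.uI[j], p.aI, p.cI);
    yT[j] = sig(s.uT[j], p.aT, p.cT);
  }
  double yS = sig(s.uS, p.aS, p.cS);
  double sumC = yC[0] + yC[1] + yC[2] + yC[3];
  double meanE = (yE[0] + yE[1] + yE[2] + yE[3]) / 4.0;

  double gGo = (1.0 + p.kD1 * D1) * p.chi;
  double gNo = (1.0 - p.kD2 * D2) * p.chi;
  if (gNo < 0.0) gNo = 0.0;

  double duC[4], duG[4], duN[4], duE[4], duI[4], duT[4];
  for (int j = 0; j < 4; ++j) {
    double sg = 0.0, sn = 0.0;
    for (int k = 0; k < 4; ++k) {
      sg += wGS(j, k) * S[k];
      sn += wNS(j, k) * S[k];
    }
    double inC = p.wCT * yT[j] + p.wCC * yC[j]
               - p.wCL * (sumC - yC[j]) + noise[j];
    double inG = gGo * (p.kS * sg + p.kC * wGC[j] * yC[j]) - p.wNG * yN[j];
    double inN = gNo * (p.kS * sn + p.kC * wNC[j] * yC[j]);
    double inE = p.bE - p.wEN * yN[j];
    double inI = p.bI + p.wIS * yS - p.wIG * yG[j] - p.wIE * yE[j];
    double inT = p.bT + p.wTC * yC[j] - p.wTI * yI[j];
    duC[j] = (-s.uC[j] + inC) / p.tauC;
    duG[j] = (-s.uG[j] + inG) / p.tauG;
    duN[j] = (-s.uN[j] + inN) / p.tauN;
    duE[j] = (-s.uE[j] + inE) / p.tauE;
    duI[j] = (-s.uI[j] + inI) / p.tauI;
    duT[j] = (-s.uT[j] + inT) / p.tauT;
  }
  double inS = p.bS + p.wSC * sumC - p.wSE * meanE;
  double duS = (-s.uS + inS) / p.tauS;
  for (int j = 0; j < 4; ++j) {
    s.uC[j] += p.dt * duC[j];
    s.uG[j] += p.dt * duG[j];
    s.uN[j] += p.dt * duN[j];
    s.uE[j] += p.dt * duE[j];
    s.uI[j] += p.dt * duI[j];
    s.uT[j] += p.dt * duT[j];
  }
  s.uS += p.dt * duS;
}

static NumericVector cortex_out(const NetState& s, const NetP& p) {
  NumericVector y(4);
  for (int j = 0; j < 4; ++j) y[j] = sig(s.uC[j], p.aC, p.cC);
  return y;
}

// Integrate one trial: settle to rest (no stimulus, no noise), then present
// the stimulus with per-step uniform cortical noise until a cortical channel
// crosses `threshold` or `duration` elapses.  Returns the choice, reaction
// time, the internal state at stopping time (for the learning-window
// continuation) and per-channel maximum cortical activity.
// [[Rcpp::export(name = ".run_trial_cpp")]]
List run_trial_cpp(NumericVector S,
                   NumericMatrix wGS, NumericMatrix wNS,
                   NumericVector wGC, NumericVector wNC,
                   List np, double D1, double D2,
                   double dt, double settle, double duration,
                   double threshold, bool noise_on = true,
                   bool trace = false) {
  NetP p = unpack(np, dt);
  NetState s;
  for (int j = 0; j < 4; ++j) {
    s.uC[j] = p.cC; s.uG[j] = p.cG; s.uN[j] = p.cN;
    s.uE[j] = p.cE; s.uI[j] = p.cI; s.uT[j] = p.cT;
  }
  s.uS = p.cS;
  double zeroS[4] = {0, 0, 0, 0};
  double zeroN[4] = {0, 0, 0, 0};
  int nset = (int) std::round(settle / dt);
  for (int i = 0; i < nset; ++i)
    net_step(s, p, zeroS, wGS, wNS, wGC, wNC, D1, D2, zeroN);

  int nstep = (int) std::round(duration / dt);
  double Sv[4];
  for (int j = 0; j < 4; ++j) Sv[j] = S[j];
  double noise[4];
  double maxC[4] = {0, 0, 0, 0};
  int chosen = 0;              // 0 = no response
  double rt = NA_REAL;
  NumericMatrix tr;
  if (trace) tr = NumericMatrix(nstep, 25);

  for (int i = 0; i < nstep; ++i) {
    for (int j = 0; j < 4; ++j)
      noise[j] = noise_on ? R::runif(0.0, p.noise) : 0.0;
    net_step(s, p, Sv, wGS, wNS, wGC, wNC, D1, D2, noise);
    NumericVector yC = cortex_out(s, p);
    for (int j = 0; j < 4; ++j) {
      if (yC[j] > maxC[j]) maxC[j] = yC[j];
      if (trace) {
        tr(i, j) = yC[j];
        tr(i, 4 + j)  = sig(s.uG[j], p.aG, p.cG);
        tr(i, 8 + j)  = sig(s.uN[j], p.aN, p.cN);
        tr(i, 12 + j) = sig(s.uE[j], p.aE, p.cE);
        tr(i, 16 + j) = sig(s.uI[j], p.aI, p.cI);
        tr(i, 20 + j) = sig(s.uT[j], p.aT, p.cT);
      }
    }
    if (trace) tr(i, 24) = sig(s.uS, p.aS, p.cS);
    if (chosen == 0) {
      int best = -1;
      for (int j = 0; j < 4; ++j)
        if (yC[j] >= threshold && (best < 0 || yC[j] > yC[best]))
          best = j;  // strict > : exact ties go to the lowest index
      if (best >= 0) {
        chosen = best + 1;
        rt = (i + 1) * dt;
        break;
      }
    }
  }

  NumericVector u(25);
  for (int j = 0; j < 4; ++j) {
    u[j] = s.uC[j];      u[4 + j] = s.uG[j];  u[8 + j] = s.uN[j];
    u[12 + j] = s.uE[j]; u[16 + j] = s.uI[j]; u[20 + j] = s.uT[j];
  }
  u[24] = s.uS;
  List out = List::create(
    _["chosen"] = chosen, _["rt"] = rt,
    _["y_cortex"] = cortex_out(s, p),
    _["max_cortex"] = NumericVector(maxC, maxC + 4),
    _["state"] = u);
  if (trace) out["trace"] = tr;
  return out;
}

// Continue a trial from a saved state through the dopamine event window:
// `lat_steps` steps at tonic occupancies (D1t, D2t), then along the supplied
// per-step occupancy traces (reward burst or punishment clamp).  Returns the
// window-averaged activities needed by the Hebb rule.
// [[Rcpp::export(name = ".run_window_cpp")]]
List run_window_cpp(NumericVector state, NumericVector S,
                    NumericMatrix wGS, NumericMatrix wNS,
                    NumericVector wGC, NumericVector wNC,
                    List np, double D1t, double D2t,
                    NumericVector D1w, NumericVector D2w,
                    double dt, int lat_steps, bool noise_on = true) {
  NetP p = unpack(np, dt);
  NetState s;
  for (int j = 0; j < 4; ++j) {
    s.uC[j] = state[j];      s.uG[j] = state[4 + j];
    s.uN[j] = state[8 + j];  s.uE[j] = state[12 + j];
    s.uI[j] = state[16 + j]; s.uT[j] = state[20 + j];
  }
  s.uS = state[24];
  double Sv[4];
  for (int j = 0; j < 4; ++j) Sv[j] = S[j];
  double noise[4];

  for (int i = 0; i < lat_steps; ++i) {
    for (int j = 0; j < 4; ++j)
      noise[j] = noise_on ? R::runif(0.0, p.noise) : 0.0;
    net_step(s, p, Sv, wGS, wNS, wGC, wNC, D1t, D2t, noise);
  }
  int nwin = D1w.size();
  double mC[4] = {0, 0, 0, 0}, mG[4] = {0, 0, 0, 0}, mN[4] = {0, 0, 0, 0};
  for (int i = 0; i < nwin; ++i) {
    for (int j = 0; j < 4; ++j)
      noise[j] = noise_on ? R::runif(0.0, p.noise) : 0.0;
    net_step(s, p, Sv, wGS, wNS, wGC, wNC, D1w[i], D2w[i], noise);
    for (int j = 0; j < 4; ++j) {
      mC[j] += sig(s.uC[j], p.aC, p.cC);
      mG[j] += sig(s.uG[j], p.aG, p.cG);
      mN[j] += sig(s.uN[j], p.aN, p.cN);
    }
  }
  for (int j = 0; j < 4; ++j) {
    mC[j] /= nwin; mG[j] /= nwin; mN[j] /= nwin;
  }
  return List::create(
    _["y_cortex"] = NumericVector(mC, mC + 4),
    _["y_go"] = NumericVector(mG, mG + 4),
    _["y_nogo"] = NumericVector(mN, mN + 4));
}
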