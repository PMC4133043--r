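// Fast fixed-step integrator for the two-layer conductance-based network.
// The R level owns construction, calibration, protocols and analysis; this
// file only advances the coupled state for a span of time with
// piecewise-constant external drive, optionally applying the two plasticity
// rules at every step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// x/(1-exp(-x)) with the removable singularity at 0 filled in.
inline double linexp(double x) {
  if (std::fabs(x) < 1e-7) return 1.0 + x / 2.0;
  return x / (1.0 - std::exp(-x));
}

// Traub-Miles style rate functions for a regular-spiking pyramidal cell.
// The sodium gates are shifted 6 mV depolarized relative to the classical
// forms so that, with the small leak conductance used here, the sodium
// window current does not destabilize the resting state near -65 mV.
inline double alpha_m(double V) { return 1.28 * linexp((V + 48.0) / 4.0); }
inline double beta_m(double V)  { return 1.4  * linexp(-(V + 21.0) / 5.0); }
inline double alpha_h(double V) { return 0.128 * std::exp(-(V + 44.0) / 18.0); }
inline double beta_h(double V)  { return 4.0 / (1.0 + std::exp(-(V + 21.0) / 5.0)); }
inline double alpha_n(double V) { return 0.16 * linexp((V + 52.0) / 5.0); }
inline double beta_n(double V)  { return 0.5 * std::exp(-(V + 57.0) / 40.0); }
// High-threshold calcium channel activation (instantaneous).
inline double mca_inf(double V) { return 1.0 / (1.0 + std::exp(-(V + 20.0) / 9.0)); }

// Piecewise-linear lookup tables for the seven voltage functions, used by
// the integrator's inner loop (the closed forms above stay authoritative
// for the exported steady-state helpers).  Grid step 0.02 mV keeps the
// interpolation error ~1e-9 on rates of order 1/ms.
struct RateTables {
  static constexpr double vmin = -130.0, vmax = 80.0, step = 0.02;
  int npt;
  std::vector<double> am, bm, ah, bh, an, bn, mca;
  RateTables() {
    npt = (int)((vmax - vmin) / step) + 2;
    am.resize(npt); bm.resize(npt); ah.resize(npt); bh.resize(npt);
    an.resize(npt); bn.resize(npt); mca.resize(npt);
    for (int i = 0; i < npt; ++i) {
      double V = vmin + i * step;
      am[i] = alpha_m(V); bm[i] = beta_m(V);
      ah[i] = alpha_h(V); bh[i] = beta_h(V);
      an[i] = alpha_n(V); bn[i] = beta_n(V);
      mca[i] = mca_inf(V);
    }
  }
};

const RateTables& rate_tables() {
  static RateTables T;
  return T;
}

struct RateLookup {
  double am, bm, ah, bh, an, bn, mca;
};

inline RateLookup lookup_rates(double V) {
  const RateTables& T = rate_tables();
  double x = (V - RateTables::vmin) / RateTables::step;
  if (std::isnan(x)) x = 0;  // caller detects the non-finite state itself
  if (x < 0) x = 0;
  if (x > T.npt - 2) x = T.npt - 2;
  int i = (int)x;
  double f = x - i;
  RateLookup r;
  r.am = T.am[i] + f * (T.am[i + 1] - T.am[i]);
  r.bm = T.bm[i] + f * (T.bm[i + 1] - T.bm[i]);
  r.ah = T.ah[i] + f * (T.ah[i + 1] - T.ah[i]);
  r.bh = T.bh[i] + f * (T.bh[i + 1] - T.bh[i]);
  r.an = T.an[i] + f * (T.an[i + 1] - T.an[i]);
  r.bn = T.bn[i] + f * (T.bn[i + 1] - T.bn[i]);
  r.mca = T.mca[i] + f * (T.mca[i + 1] - T.mca[i]);
  return r;
}

struct HHParams {
  double gL, gNa, gK, gCa, gAHP, VL, VNa, VK, VCa, tauCa;
  bool has_ahp;
};

HHParams read_params(const List& p) {
  HHParams q;
  q.gL = as<double>(p["g_L"]);
  q.gNa = as<double>(p["g_Na"]);
  q.gK = as<double>(p["g_K"]);
  q.gCa = as<double>(p["g_Ca"]);
  q.gAHP = as<double>(p["g_AHP"]);
  q.VL = as<double>(p["V_L"]);
  q.VNa = as<double>(p["V_Na"]);
  q.VK = as<double>(p["V_K"]);
  q.VCa = as<double>(p["V_Ca"]);
  q.tauCa = as<double>(p["tau_Ca"]);
  q.has_ahp = as<bool>(p["has_ahp"]);
  return q;
}

struct Deriv { double dV, dm, dh, dn, dCa; };

// Membrane derivative with synaptic conductances held fixed over the step.
// Currents follow the g * (E - V) convention, so positive values depolarize.
inline Deriv hh_deriv(const HHParams& p, double V, double m, double h,
                      double n, double Ca, double ge, double gi,
                      double Vee, double Vie, double Iinj) {
  Deriv d;
  RateLookup r = lookup_rates(V);
  double I = p.gL * (p.VL - V)
    + p.gNa * m * m * m * h * (p.VNa - V)
    + p.gK * n * n * n * n * (p.VK - V)
    + p.gCa * r.mca * r.mca * (p.VCa - V)
    + ge * (Vee - V)
    + gi * (Vie - V)
    + Iinj;
  if (p.has_ahp) I += p.gAHP * Ca * (p.VK - V);
  d.dV = I;  // C = 1
  d.dm = r.am * (1.0 - m) - r.bm * m;
  d.dh = r.ah * (1.0 - h) - r.bh * h;
  d.dn = r.an * (1.0 - n) - r.bn * n;
  d.dCa = -Ca / p.tauCa;
  return d;
}

// Classical RK4 for one neuron over one dt.
inline void rk4_step(const HHParams& p, double& V, double& m, double& h,
                     double& n, double& Ca, double ge, double gi,
                     double Vee, double Vie, double Iinj, double dt) {
  Deriv k1 = hh_deriv(p, V, m, h, n, Ca, ge, gi, Vee, Vie, Iinj);
  Deriv k2 = hh_deriv(p, V + 0.5 * dt * k1.dV, m + 0.5 * dt * k1.dm,
                      h + 0.5 * dt * k1.dh, n + 0.5 * dt * k1.dn,
                      Ca + 0.5 * dt * k1.dCa, ge, gi, Vee, Vie, Iinj);
  Deriv k3 = hh_deriv(p, V + 0.5 * dt * k2.dV, m + 0.5 * dt * k2.dm,
                      h + 0.5 * dt * k2.dh, n + 0.5 * dt * k2.dn,
                      Ca + 0.5 * dt * k2.dCa, ge, gi, Vee, Vie, Iinj);
  Deriv k4 = hh_deriv(p, V + dt * k3.dV, m + dt * k3.dm, h + dt * k3.dh,
                      n + dt * k3.dn, Ca + dt * k3.dCa, ge, gi, Vee, Vie, Iinj);
  V += dt / 6.0 * (k1.dV + 2 * k2.dV + 2 * k3.dV + k4.dV);
  m += dt / 6.0 * (k1.dm + 2 * k2.dm + 2 * k3.dm + k4.dm);
  h += dt / 6.0 * (k1.dh + 2 * k2.dh + 2 * k3.dh + k4.dh);
  n += dt / 6.0 * (k1.dn + 2 * k2.dn + 2 * k3.dn + k4.dn);
  Ca += dt / 6.0 * (k1.dCa + 2 * k2.dCa + 2 * k3.dCa + k4.dCa);
  if (m < 0) m = 0; else if (m > 1) m = 1;
  if (h < 0) h = 0; else if (h > 1) h = 1;
  if (n < 0) n = 0; else if (n > 1) n = 1;
  if (Ca < 0) Ca = 0;
}

}  // namespace

// Steady-state gating at a fixed voltage; used to initialize resting states.
// [[Rcpp::export]]
NumericVector hh_gating_inf_cpp(double V) {
  return NumericVector::create(
    _["m"] = alpha_m(V) / (alpha_m(V) + beta_m(V)),
    _["h"] = alpha_h(V) / (alpha_h(V) + beta_h(V)),
    _["n"] = alpha_n(V) / (alpha_n(V) + beta_n(V)));
}

// Total membrane current at fixed V with gating at steady state (root of this
// in V is the resting potential).  Exposed for the resting-state oracle.
// [[Rcpp::export]]
double hh_steady_current_cpp(List params, double V, double Ca, double ge,
                             double gi, double Vee, double Vie, double Iinj) {
  HHParams p = read_params(params);
  double m = alpha_m(V) / (alpha_m(V) + beta_m(V));
  double h = alpha_h(V) / (alpha_h(V) + beta_h(V));
  double n = alpha_n(V) / (alpha_n(V) + beta_n(V));
  Deriv d = hh_deriv(p, V, m, h, n, Ca, ge, gi, Vee, Vie, Iinj);
  return d.dV;
}

// Single-neuron simulation with fixed synaptic conductances and injected
// current.  Used by unit tests and by the f-I machinery on isolated cells.
// [[Rcpp::export]]
List simulate_neuron_cpp(List params, List state0, double ge, double gi,
                         double Vee, double Vie, double Iinj, double duration,
                         double dt, double ca_inc, double refrac,
                         int record_every) {
  HHParams p = read_params(params);
  double V = as<double>(state0["V"]), m = as<double>(state0["m"]);
  double h = as<double>(state0["h"]), n = as<double>(state0["n"]);
  double Ca = as<double>(state0["Ca"]);
  double last = as<double>(state0["last_spike"]);
  int nsteps = (int)std::llround(duration / dt);
  std::vector<double> spikes;
  std::vector<double> tv, Vv, Cav;
  for (int s = 0; s < nsteps; ++s) {
    double t = s * dt;
    if (record_every > 0 && s % record_every == 0) {
      tv.push_back(t); Vv.push_back(V); Cav.push_back(Ca);
    }
    double Vold = V;
    rk4_step(p, V, m, h, n, Ca, ge, gi, Vee, Vie, Iinj, dt);
    if (!std::isfinite(V))
      stop("integration diverged at t = %f ms", t);
    double tnew = t + dt;
    if (Vold < 0.0 && V >= 0.0 && (ISNA(last) || tnew - last >= refrac)) {
      spikes.push_back(tnew);
      last = tnew;
      Ca += ca_inc;
    }
  }
  List st = List::create(_["V"] = V, _["m"] = m, _["h"] = h, _["n"] = n,
                         _["Ca"] = Ca, _["last_spike"] = last);
  return List::create(_["spikes"] = wrap(spikes), _["state"] = st,
                      _["time"] = wrap(tv), _["V"] = wrap(Vv),
                      _["Ca"] = wrap(Cav));
}

// Advance the full two-layer network.
//
// net:   list built by build_network() (weights, parameter sets, synapse and
//        plasticity constants).
// state: list built by init_state() / returned by a previous call.
// I_e1, I_i1, I_e2: external injected current per neuron, constant over the
//        call (bell-shaped stimulus plus any probe current).
// plastic_ff / plastic_fb: apply the Hebbian / homeostatic rule each step.
// record_e1: 1-based indices of V1 excitatory neurons whose voltage and
//        decomposed synaptic currents (and conductances) are recorded every
//        `record_every` steps.
// [[Rcpp::export]]
List advance_cpp(List net, List state, NumericVector I_e1, NumericVector I_i1,
                 NumericVector I_e2, double duration, double dt,
                 bool plastic_ff, bool plastic_fb, NumericVector ca_target,
                 IntegerVector record_e1, int record_every) {
  const int Ne1 = as<int>(net["n_v1_e"]);
  const int Ni1 = as<int>(net["n_v1_i"]);
  const int Ne2 = as<int>(net["n_v2_e"]);
  NumericMatrix W_EE = net["W_EE"], W_EI = net["W_EI"], W_IE = net["W_IE"],
                W_II = net["W_II"];
  NumericMatrix W_FF = clone(as<NumericMatrix>(net["W_FF"]));
  LogicalMatrix M_FF = net["M_FF"];
  NumericVector w_fb = clone(as<NumericVector>(net["w_fb"]));
  const double fb_to_i = as<double>(net["fb_to_i"]);
  HHParams pe = read_params(net["params_e"]);
  HHParams pi = read_params(net["params_i"]);
  List syn = net["syn"];
  const double tau_ampa = as<double>(syn["tau_ampa"]);
  const double tau_gabaa = as<double>(syn["tau_gabaa"]);
  const double Vee = as<double>(syn["V_ee"]);
  const double Vei = as<double>(syn["V_ei"]);
  const double Vie = as<double>(syn["V_ie"]);
  const double f_e = as<double>(syn["f_e"]);
  const double f_i = as<double>(syn["f_i"]);
  const double ca_inc = as<double>(net["ca_inc"]);
  const double refrac = as<double>(net["refrac"]);
  List pl = net["plasticity"];
  const double eta_hebb = as<double>(pl["eta_hebb"]);
  const double tau_hebb = as<double>(pl["tau_hebb"]);
  const double w_ff_max = as<double>(pl["w_ff_max"]);
  const double eta_fb = as<double>(pl["eta_fb"]);
  const double tau_fb = as<double>(pl["tau_fb"]);
  const double w_fb_max = as<double>(pl["w_fb_max"]);

  if (I_e1.size() != Ne1 || I_i1.size() != Ni1 || I_e2.size() != Ne2)
    stop("external current vector length does not match population size");
  if (plastic_fb && ca_target.size() != Ne2)
    stop("ca_target must have one entry per V2 neuron");

  // working copies of the state
  NumericVector Ve1 = clone(as<NumericVector>(state["V_e1"]));
  NumericVector me1 = clone(as<NumericVector>(state["m_e1"]));
  NumericVector he1 = clone(as<NumericVector>(state["h_e1"]));
  NumericVector ne1 = clone(as<NumericVector>(state["n_e1"]));
  NumericVector Cae1 = clone(as<NumericVector>(state["Ca_e1"]));
  NumericVector lse1 = clone(as<NumericVector>(state["last_e1"]));
  NumericVector Vi1 = clone(as<NumericVector>(state["V_i1"]));
  NumericVector mi1 = clone(as<NumericVector>(state["m_i1"]));
  NumericVector hi1 = clone(as<NumericVector>(state["h_i1"]));
  NumericVector ni1 = clone(as<NumericVector>(state["n_i1"]));
  NumericVector Cai1 = clone(as<NumericVector>(state["Ca_i1"]));
  NumericVector lsi1 = clone(as<NumericVector>(state["last_i1"]));
  NumericVector Ve2 = clone(as<NumericVector>(state["V_e2"]));
  NumericVector me2 = clone(as<NumericVector>(state["m_e2"]));
  NumericVector he2 = clone(as<NumericVector>(state["h_e2"]));
  NumericVector ne2 = clone(as<NumericVector>(state["n_e2"]));
  NumericVector Cae2 = clone(as<NumericVector>(state["Ca_e2"]));
  NumericVector lse2 = clone(as<NumericVector>(state["last_e2"]));
  NumericVector se1 = clone(as<NumericVector>(state["s_e1"]));
  NumericVector si1 = clone(as<NumericVector>(state["s_i1"]));
  NumericVector se2 = clone(as<NumericVector>(state["s_e2"]));
  double t0 = as<double>(state["t"]);

  const int nsteps = (int)std::llround(duration / dt);
  const double dec_e = std::exp(-dt / tau_ampa);
  const double dec_i = std::exp(-dt / tau_gabaa);

  // precompute feedforward sparsity as index lists
  std::vector<int> ff_post, ff_pre;
  for (int i = 0; i < Ne2; ++i)
    for (int j = 0; j < Ne1; ++j)
      if (M_FF(i, j)) { ff_post.push_back(i); ff_pre.push_back(j); }

  // spike storage
  std::vector<double> spk_t_e1, spk_t_i1, spk_t_e2;
  std::vector<int> spk_id_e1, spk_id_i1, spk_id_e2;

  // trace storage for recorded V1 E neurons
  const int nrec = record_e1.size();
  const int ntr = (record_every > 0 && nrec > 0)
    ? (nsteps + record_every - 1) / record_every : 0;
  NumericVector tr_time(ntr);
  NumericMatrix tr_V(ntr, nrec), tr_Iexc(ntr, nrec), tr_Iinh(ntr, nrec),
                tr_gexc(ntr, nrec), tr_ginh(ntr, nrec);

  // running sums for time-averaged quantities
  double sum_fb_drive = 0.0, sum_ca2 = 0.0;
  std::vector<double> sum_ca2_i(Ne2, 0.0), sum_ca1_i(Ne1, 0.0);
  std::vector<double> sum_ge_rec(nrec, 0.0), sum_gi_rec(nrec, 0.0);

  std::vector<double> ge_e1(Ne1), gi_e1(Ne1), ge_i1(Ni1), gi_i1(Ni1), ge_e2(Ne2);
  std::vector<int> spikers_e1, spikers_i1, spikers_e2;

  for (int s = 0; s < nsteps; ++s) {
    double t = t0 + s * dt;

    // synaptic conductances from start-of-step gating; sources whose gating
    // has decayed to nothing are skipped (columns of the column-major
    // weight matrices are walked sequentially for the active sources only)
    double fb_drive = 0.0;
    for (int i = 0; i < Ne2; ++i) fb_drive += w_fb[i] * se2[i];
    std::fill(ge_e1.begin(), ge_e1.end(), 0.0);
    std::fill(gi_e1.begin(), gi_e1.end(), 0.0);
    std::fill(ge_i1.begin(), ge_i1.end(), 0.0);
    std::fill(gi_i1.begin(), gi_i1.end(), 0.0);
    std::fill(ge_e2.begin(), ge_e2.end(), 0.0);
    const double* pEE = REAL(W_EE);
    const double* pEI = REAL(W_EI);
    const double* pIE = REAL(W_IE);
    const double* pII = REAL(W_II);
    const double* pFF = REAL(W_FF);
    for (int j = 0; j < Ne1; ++j) {
      double s = se1[j];
      if (s < 1e-12) continue;
      const double* cEE = pEE + (size_t)j * Ne1;
      for (int k = 0; k < Ne1; ++k) ge_e1[k] += cEE[k] * s;
      const double* cEI = pEI + (size_t)j * Ni1;
      for (int k = 0; k < Ni1; ++k) ge_i1[k] += cEI[k] * s;
      const double* cFF = pFF + (size_t)j * Ne2;
      for (int k = 0; k < Ne2; ++k) ge_e2[k] += cFF[k] * s;
    }
    for (int j = 0; j < Ni1; ++j) {
      double s = si1[j];
      if (s < 1e-12) continue;
      const double* cIE = pIE + (size_t)j * Ne1;
      for (int k = 0; k < Ne1; ++k) gi_e1[k] += cIE[k] * s;
      const double* cII = pII + (size_t)j * Ni1;
      for (int k = 0; k < Ni1; ++k) gi_i1[k] += cII[k] * s;
    }
    for (int k = 0; k < Ne1; ++k) {
      ge_e1[k] = f_e * (ge_e1[k] + fb_drive);
      gi_e1[k] *= f_i;
    }
    for (int k = 0; k < Ni1; ++k) {
      ge_i1[k] = f_e * (ge_i1[k] + fb_to_i * fb_drive);
      gi_i1[k] *= f_i;
    }
    for (int k = 0; k < Ne2; ++k) ge_e2[k] *= f_e;

    // record traces (currents evaluated at start-of-step V, resting-free form)
    if (ntr > 0 && s % record_every == 0) {
      int r = s / record_every;
      tr_time[r] = t;
      for (int q = 0; q < nrec; ++q) {
        int k = record_e1[q] - 1;
        tr_V(r, q) = Ve1[k];
        tr_gexc(r, q) = ge_e1[k];
        tr_ginh(r, q) = gi_e1[k];
        tr_Iexc(r, q) = ge_e1[k] * (Vee - Ve1[k]);
        tr_Iinh(r, q) = gi_e1[k] * (Vie - Ve1[k]);
      }
    }
    for (int q = 0; q < nrec; ++q) {
      int k = record_e1[q] - 1;
      sum_ge_rec[q] += ge_e1[k];
      sum_gi_rec[q] += gi_e1[k];
    }
    sum_fb_drive += fb_drive;

    // advance neurons
    spikers_e1.clear(); spikers_i1.clear(); spikers_e2.clear();
    double tnew = t + dt;
    for (int k = 0; k < Ne1; ++k) {
      double Vold = Ve1[k];
      rk4_step(pe, Ve1[k], me1[k], he1[k], ne1[k], Cae1[k], ge_e1[k], gi_e1[k],
               Vee, Vie, I_e1[k], dt);
      if (!std::isfinite(Ve1[k]))
        stop("integration diverged: V1 excitatory neuron %d at t = %f", k + 1, t);
      if (Vold < 0.0 && Ve1[k] >= 0.0 &&
          (ISNA(lse1[k]) || tnew - lse1[k] >= refrac)) {
        spikers_e1.push_back(k); lse1[k] = tnew; Cae1[k] += ca_inc;
        spk_t_e1.push_back(tnew); spk_id_e1.push_back(k + 1);
      }
    }
    for (int k = 0; k < Ni1; ++k) {
      double Vold = Vi1[k];
      rk4_step(pi, Vi1[k], mi1[k], hi1[k], ni1[k], Cai1[k], ge_i1[k], gi_i1[k],
               Vei, Vie, I_i1[k], dt);
      if (!std::isfinite(Vi1[k]))
        stop("integration diverged: V1 inhibitory neuron %d at t = %f", k + 1, t);
      if (Vold < 0.0 && Vi1[k] >= 0.0 &&
          (ISNA(lsi1[k]) || tnew - lsi1[k] >= refrac)) {
        spikers_i1.push_back(k); lsi1[k] = tnew; Cai1[k] += ca_inc;
        spk_t_i1.push_back(tnew); spk_id_i1.push_back(k + 1);
      }
    }
    for (int k = 0; k < Ne2; ++k) {
      double Vold = Ve2[k];
      rk4_step(pe, Ve2[k], me2[k], he2[k], ne2[k], Cae2[k], ge_e2[k], 0.0,
               Vee, Vie, I_e2[k], dt);
      if (!std::isfinite(Ve2[k]))
        stop("integration diverged: V2 neuron %d at t = %f", k + 1, t);
      if (Vold < 0.0 && Ve2[k] >= 0.0 &&
          (ISNA(lse2[k]) || tnew - lse2[k] >= refrac)) {
        spikers_e2.push_back(k); lse2[k] = tnew; Cae2[k] += ca_inc;
        spk_t_e2.push_back(tnew); spk_id_e2.push_back(k + 1);
      }
    }

    // synaptic gating: exponential decay, then unit increments on spikes
    for (int k = 0; k < Ne1; ++k) se1[k] *= dec_e;
    for (int k = 0; k < Ni1; ++k) si1[k] *= dec_i;
    for (int k = 0; k < Ne2; ++k) se2[k] *= dec_e;
    for (size_t q = 0; q < spikers_e1.size(); ++q) se1[spikers_e1[q]] += 1.0;
    for (size_t q = 0; q < spikers_i1.size(); ++q) si1[spikers_i1[q]] += 1.0;
    for (size_t q = 0; q < spikers_e2.size(); ++q) se2[spikers_e2[q]] += 1.0;

    // plasticity
    if (plastic_ff) {
      for (size_t c = 0; c < ff_post.size(); ++c) {
        int i = ff_post[c], j = ff_pre[c];
        double w = W_FF(i, j) +
          dt * eta_hebb * Cae1[j] * Cae2[i] / tau_hebb;
        W_FF(i, j) = (w > w_ff_max) ? w_ff_max : w;
      }
    }
    if (plastic_fb) {
      for (int i = 0; i < Ne2; ++i) {
        double w = w_fb[i] + dt * eta_fb * (Cae2[i] - ca_target[i]) / tau_fb;
        if (w < 0) w = 0; else if (w > w_fb_max) w = w_fb_max;
        w_fb[i] = w;
      }
    }

    double mc = 0.0;
    for (int i = 0; i < Ne2; ++i) { mc += Cae2[i]; sum_ca2_i[i] += Cae2[i]; }
    for (int j = 0; j < Ne1; ++j) sum_ca1_i[j] += Cae1[j];
    sum_ca2 += mc / Ne2;
  }

  List st = List::create(
    _["V_e1"] = Ve1, _["m_e1"] = me1, _["h_e1"] = he1, _["n_e1"] = ne1,
    _["Ca_e1"] = Cae1, _["last_e1"] = lse1,
    _["V_i1"] = Vi1, _["m_i1"] = mi1, _["h_i1"] = hi1, _["n_i1"] = ni1,
    _["Ca_i1"] = Cai1, _["last_i1"] = lsi1,
    _["V_e2"] = Ve2, _["m_e2"] = me2, _["h_e2"] = he2, _["n_e2"] = ne2,
    _["Ca_e2"] = Cae2, _["last_e2"] = lse2,
    _["s_e1"] = se1, _["s_i1"] = si1, _["s_e2"] = se2,
    _["t"] = t0 + nsteps * dt);

  NumericVector mca2(Ne2), mca1(Ne1), mge(nrec), mgi(nrec);
  for (int i = 0; i < Ne2; ++i) mca2[i] = sum_ca2_i[i] / nsteps;
  for (int j = 0; j < Ne1; ++j) mca1[j] = sum_ca1_i[j] / nsteps;
  for (int q = 0; q < nrec; ++q) {
    mge[q] = sum_ge_rec[q] / nsteps;
    mgi[q] = sum_gi_rec[q] / nsteps;
  }

  List traces = List::create(
    _["time"] = tr_time, _["V"] = tr_V, _["I_exc"] = tr_Iexc,
    _["I_inh"] = tr_Iinh, _["g_exc"] = tr_gexc, _["g_inh"] = tr_ginh,
    _["neuron"] = record_e1);

  return List::create(
    _["state"] = st,
    _["spikes_e1"] = DataFrame::create(_["time"] = wrap(spk_t_e1),
                                       _["neuron"] = wrap(spk_id_e1)),
    _["spikes_i1"] = DataFrame::create(_["time"] = wrap(spk_t_i1),
                                       _["neuron"] = wrap(spk_id_i1)),
    _["spikes_e2"] = DataFrame::create(_["time"] = wrap(spk_t_e2),
                                       _["neuron"] = wrap(spk_id_e2)),
    _["traces"] = traces,
    _["W_FF"] = W_FF, _["w_fb"] = w_fb,
    _["mean_fb_drive"] = sum_fb_drive / nsteps,
    _["mean_ca_v2"] = sum_ca2 / nsteps,
    _["mean_ca_v2_per_neuron"] = mca2,
    _["mean_ca_v1_per_neuron"] = mca1,
    _["mean_g_exc"] = mge, _["mean_g_inh"] = mgi);
}
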