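// Network integration core.
//
// Units (repo-wide): time ms, voltage mV, current nA, conductance uS,
// capacitance nF, position um.  With these units C dV/dt = I holds as
// nF * mV/ms = nA, and I = g*(V - E) as uS * mV = nA.
//
// Integration scheme: exponential Euler for gating variables (tabulated
// steady state / step factor on a 0.05 mV voltage grid, rebuilt for each dt),
// implicit Euler in voltage with a Hines (tree tridiagonal) solve per cell.
// Synapses are bi-exponential conductances aggregated per target compartment
// into a small number of receptor classes, so per-step cost is independent of
// synapse count; spikes deposit increments into the class states through a
// delay ring buffer.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const double V_MIN = -120.0, V_MAX = 60.0, V_STEP = 0.05;
const int NV = (int)((V_MAX - V_MIN) / V_STEP) + 1;

inline double vtrap(double x, double y) {
  // x/(1 - exp(-x/y)) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (1.0 - std::exp(-x / y));
}

struct RateFn {
  // alpha/beta pairs for the classic formalism
  virtual void rates(double v, double &a, double &b) const = 0;
  virtual ~RateFn() {}
};

// Traub-type regular-spiking kinetics (pyr and most interneurons)
struct TraubNaM : RateFn { void rates(double v, double &a, double &b) const {
  a = 0.32 * vtrap(v + 54.0, 4.0);
  b = 0.28 * vtrap(-(v + 27.0), 5.0);
} };
struct TraubNaH : RateFn { void rates(double v, double &a, double &b) const {
  a = 0.128 * std::exp(-(v + 50.0) / 18.0);
  b = 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0));
} };
struct TraubKn : RateFn { void rates(double v, double &a, double &b) const {
  a = 0.032 * vtrap(v + 52.0, 5.0);
  b = 0.5 * std::exp(-(v + 57.0) / 40.0);
} };

// Wang-Buzsaki fast-spiking kinetics (pvbas, aac); phi = 5
struct WBNaM : RateFn { void rates(double v, double &a, double &b) const {
  a = 0.1 * vtrap(v + 35.0, 10.0);
  b = 4.0 * std::exp(-(v + 60.0) / 18.0);
} };
struct WBNaH : RateFn { void rates(double v, double &a, double &b) const {
  a = 5.0 * 0.07 * std::exp(-(v + 58.0) / 20.0);
  b = 5.0 / (1.0 + std::exp(-(v + 28.0) / 10.0));
} };
struct WBKn : RateFn { void rates(double v, double &a, double &b) const {
  a = 5.0 * 0.01 * vtrap(v + 34.0, 10.0);
  b = 5.0 * 0.125 * std::exp(-(v + 44.0) / 80.0);
} };

struct GateTable {
  std::vector<double> inf, k; // steady state, 1 - exp(-dt/tau)
  void build(const RateFn &fn, double dt) {
    inf.resize(NV); k.resize(NV);
    for (int i = 0; i < NV; ++i) {
      double v = V_MIN + i * V_STEP, a, b;
      fn.rates(v, a, b);
      double tau = 1.0 / (a + b);
      inf[i] = a * tau;
      k[i] = 1.0 - std::exp(-dt / tau);
    }
  }
  // direct inf/tau variant (K-M, H current)
  void build_inftau(double dt, bool km) {
    inf.resize(NV); k.resize(NV);
    for (int i = 0; i < NV; ++i) {
      double v = V_MIN + i * V_STEP, minf, tau;
      if (km) { // muscarinic K (adaptation), Yamada-type
        minf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
        tau = 1000.0 / (3.3 * (std::exp((v + 35.0) / 20.0) +
                               std::exp(-(v + 35.0) / 20.0)));
      } else {  // H current (OLM sag/rebound)
        minf = 1.0 / (1.0 + std::exp((v + 80.0) / 10.0));
        tau = 200.0 / (std::exp((v + 70.0) / 20.0) +
                       std::exp(-(v + 70.0) / 20.0)) + 5.0;
      }
      inf[i] = minf;
      k[i] = 1.0 - std::exp(-dt / tau);
    }
  }
  inline void step(double v, double &x) const {
    double u = (v - V_MIN) / V_STEP;
    if (u < 0) u = 0;
    if (u > NV - 1.001) u = NV - 1.001;
    int i = (int)u;
    double f = u - i;
    double xi = inf[i] + f * (inf[i + 1] - inf[i]);
    double kk = k[i] + f * (k[i + 1] - k[i]);
    x += (xi - x) * kk;
  }
};

inline int iv(List x, const char *n) { return as<int>(x[n]); }
inline double dv(List x, const char *n) { return as<double>(x[n]); }

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List net) {
  const double dt = dv(net, "dt");
  const long n_steps = (long)dv(net, "n_steps");
  const double t0 = net.containsElementNamed("t0") ? dv(net, "t0") : 0.0;

  // --- compartments -------------------------------------------------------
  NumericVector C_nF = net["C_nF"], gL = net["gL"], EL = net["EL"],
                gNa = net["gNa"], gKdr = net["gKdr"], gKM = net["gKM"],
                gH = net["gH"], g_ax = net["g_axial"];
  IntegerVector kin = net["kin"], parent = net["parent"], cellof = net["cell"];
  const int ncomp = C_nF.size();

  const double ENa_tr = 50.0, ENa_wb = 55.0, EK = -90.0, EH = -30.0;

  // --- cells --------------------------------------------------------------
  IntegerVector comp0 = net["comp_start"], comp1 = net["comp_end"],
                soma = net["soma_comp"];
  NumericVector thresh = net["thresh"];
  const double refrac = dv(net, "refrac");
  const int ncell = soma.size();

  // --- synapse receptor classes -------------------------------------------
  NumericVector syn_tr = net["syn_tau_rise"], syn_td = net["syn_tau_decay"],
                syn_E = net["syn_E"];
  const int nslot = syn_tr.size();
  std::vector<double> dec_r(nslot), dec_d(nslot), syn_norm(nslot);
  for (int s = 0; s < nslot; ++s) {
    dec_r[s] = std::exp(-dt / syn_tr[s]);
    dec_d[s] = std::exp(-dt / syn_td[s]);
    double tp = syn_tr[s] * syn_td[s] / (syn_td[s] - syn_tr[s]) *
                std::log(syn_td[s] / syn_tr[s]);
    syn_norm[s] = std::exp(-tp / syn_td[s]) - std::exp(-tp / syn_tr[s]);
  }

  // --- connections (CSR over presynaptic units: cells then generators) ----
  IntegerVector cptr = net["conn_ptr"], ccomp = net["conn_comp"],
                cslot = net["conn_slot"], cdel = net["conn_delay"];
  NumericVector cw = net["conn_w"];
  const int nunit = cptr.size() - 1;

  // --- generator spikes (pre-sampled, sorted by step) ---------------------
  IntegerVector gstep = net["gen_spike_step"], gid = net["gen_spike_unit"];
  const long ngs = gstep.size();

  // --- gap junctions ------------------------------------------------------
  IntegerVector gj_i = net["gj_i"], gj_j = net["gj_j"];
  NumericVector gj_g = net["gj_g"];
  const int ngj = gj_i.size();

  // --- injected drive currents --------------------------------------------
  NumericVector I0 = net["I_tonic"], Iamp = net["I_rhythm_amp"],
                Iph = net["I_rhythm_phase"];
  const double f_drive = dv(net, "f_drive"); // Hz

  // --- recording ----------------------------------------------------------
  IntegerVector vm_comp = net["vm_comp"];
  const int sample_every = iv(net, "sample_every");
  IntegerVector cur_src = net["cur_src"];
  const int n_src = iv(net, "n_src");
  const bool rec_spikes = as<bool>(net["record_spikes"]);

  // --- gating tables -------------------------------------------------------
  GateTable t_m, t_h, t_n, w_m, w_h, w_n, km_t, h_t;
  t_m.build(TraubNaM(), dt); t_h.build(TraubNaH(), dt); t_n.build(TraubKn(), dt);
  w_m.build(WBNaM(), dt); w_h.build(WBNaH(), dt); w_n.build(WBKn(), dt);
  // Wang-Buzsaki Na activation is instantaneous (m = m_inf); a relaxing m
  // puts the fast-spiking model into depolarization block
  for (int i = 0; i < NV; ++i) w_m.k[i] = 1.0;
  km_t.build_inftau(dt, true); h_t.build_inftau(dt, false);

  // --- state ---------------------------------------------------------------
  std::vector<double> V(ncomp), m(ncomp), h(ncomp), n(ncomp), mkm(ncomp),
      qh(ncomp);
  std::vector<double> xr(ncomp * nslot, 0.0), xd(ncomp * nslot, 0.0);
  std::vector<double> last_spk(ncell, -1e18);
  std::vector<char> armed(ncell, 1);

  bool has_state = net.containsElementNamed("state_in") &&
                   !Rf_isNull(net["state_in"]);
  if (has_state) {
    List st = net["state_in"];
    NumericVector sv = st["V"], sm = st["m"], sh = st["h"], sn = st["n"],
                  skm = st["mkm"], sq = st["qh"], sxr = st["xr"], sxd = st["xd"],
                  sls = st["last_spike"];
    for (int i = 0; i < ncomp; ++i) {
      V[i] = sv[i]; m[i] = sm[i]; h[i] = sh[i]; n[i] = sn[i];
      mkm[i] = skm[i]; qh[i] = sq[i];
      if (!R_finite(V[i]))
        stop("non-finite voltage in initial state at compartment %d", i + 1);
    }
    for (int i = 0; i < ncomp * nslot; ++i) { xr[i] = sxr[i]; xd[i] = sxd[i]; }
    for (int c = 0; c < ncell; ++c) last_spk[c] = sls[c];
  } else {
    NumericVector V0 = net["V0"];
    for (int i = 0; i < ncomp; ++i) {
      V[i] = V0[i];
      // gating at steady state for V0
      double u = V[i]; double a, b;
      TraubNaM().rates(u, a, b); m[i] = a / (a + b);
      TraubNaH().rates(u, a, b); h[i] = a / (a + b);
      TraubKn().rates(u, a, b);  n[i] = a / (a + b);
      if (kin[i] == 1) {
        WBNaM().rates(u, a, b); m[i] = a / (a + b);
        WBNaH().rates(u, a, b); h[i] = a / (a + b);
        WBKn().rates(u, a, b);  n[i] = a / (a + b);
      }
      mkm[i] = 1.0 / (1.0 + std::exp(-(u + 35.0) / 10.0));
      qh[i] = 1.0 / (1.0 + std::exp((u + 80.0) / 10.0));
    }
  }

  for (int c = 0; c < ncell; ++c) armed[c] = (V[soma[c]] < thresh[c]) ? 1 : 0;

  // --- delay ring buffer ---------------------------------------------------
  int maxd = 1;
  for (int i = 0; i < cdel.size(); ++i) if (cdel[i] > maxd) maxd = cdel[i];
  const int ring = maxd + 1;
  std::vector<std::vector<std::pair<int, double>>> queue(ring);

  // scratch for Hines solve
  std::vector<double> diag(ncomp), rhs(ncomp), Gtot(ncomp), GEsum(ncomp),
      Iext(ncomp), Imem(ncomp);

  // outputs
  std::vector<double> spk_t; std::vector<int> spk_cell;
  const long n_samp = n_steps / (sample_every > 0 ? sample_every : 1);
  NumericMatrix vm_out(vm_comp.size() > 0 ? n_samp : 0, vm_comp.size());
  NumericMatrix cur_out(n_src > 0 ? n_samp : 0, n_src);
  std::vector<double> cur_acc(n_src > 0 ? n_src : 1, 0.0);
  long samp_i = 0;

  long gp = 0; // generator spike pointer
  const double two_pi = 2.0 * M_PI;

  for (long s = 0; s < n_steps; ++s) {
    double t = t0 + s * dt;
    int slot_now = (int)(s % ring);

    // deliver queued synaptic events
    for (auto &ev : queue[slot_now]) {
      int idx = ev.first;
      xr[idx] += ev.second; xd[idx] += ev.second;
    }
    queue[slot_now].clear();

    // schedule generator spikes occurring at this step
    while (gp < ngs && gstep[gp] == s) {
      int u = gid[gp];
      for (int c = cptr[u]; c < cptr[u + 1]; ++c) {
        int at = (int)((s + cdel[c]) % ring);
        queue[at].push_back({ccomp[c] * nslot + cslot[c], cw[c] / syn_norm[cslot[c]]});
      }
      ++gp;
    }

    // synaptic decay + conductance/current accumulation
    double cosdrv = std::cos(two_pi * f_drive * t / 1000.0);
    double sindrv = std::sin(two_pi * f_drive * t / 1000.0);
    for (int i = 0; i < ncomp; ++i) {
      double G = gL[i], GE = gL[i] * EL[i];
      double *pr = &xr[(size_t)i * nslot], *pd = &xd[(size_t)i * nslot];
      for (int sl = 0; sl < nslot; ++sl) {
        pr[sl] *= dec_r[sl]; pd[sl] *= dec_d[sl];
        double g = pd[sl] - pr[sl];
        if (g > 0) { G += g; GE += g * syn_E[sl]; }
      }
      // gating update (exponential Euler from tables), ionic conductances
      double v = V[i];
      if (gNa[i] > 0.0) {
        if (kin[i] == 1) { w_m.step(v, m[i]); w_h.step(v, h[i]); w_n.step(v, n[i]); }
        else             { t_m.step(v, m[i]); t_h.step(v, h[i]); t_n.step(v, n[i]); }
        double gna = gNa[i] * m[i] * m[i] * m[i] * h[i];
        double gk = gKdr[i] * n[i] * n[i] * n[i] * n[i];
        double ena = (kin[i] == 1) ? ENa_wb : ENa_tr;
        G += gna + gk; GE += gna * ena + gk * EK;
      }
      if (gKM[i] > 0.0) {
        km_t.step(v, mkm[i]);
        double g = gKM[i] * mkm[i];
        G += g; GE += g * EK;
      }
      if (gH[i] > 0.0) {
        h_t.step(v, qh[i]);
        double g = gH[i] * qh[i];
        G += g; GE += g * EH;
      }
      double ie = I0[i];
      if (Iamp[i] != 0.0)
        ie += Iamp[i] * 0.5 *
              (1.0 + cosdrv * std::cos(Iph[i]) - sindrv * std::sin(Iph[i]));
      Iext[i] = ie;
      Gtot[i] = G; GEsum[i] = GE;
    }

    // gap junctions (explicit)
    for (int g = 0; g < ngj; ++g) {
      double Ig = gj_g[g] * (V[gj_j[g]] - V[gj_i[g]]);
      Iext[gj_i[g]] += Ig; Iext[gj_j[g]] -= Ig;
    }

    // Hines solve per cell: (C/dt + G + sum a) V' - a V'_par - sum a V'_child = rhs
    for (int i = 0; i < ncomp; ++i) {
      diag[i] = C_nF[i] / dt + Gtot[i];
      rhs[i] = C_nF[i] / dt * V[i] + GEsum[i] + Iext[i];
      if (parent[i] >= 0) { diag[i] += g_ax[i]; diag[parent[i]] += g_ax[i]; }
    }
    for (int i = ncomp - 1; i >= 0; --i) {
      int p = parent[i];
      if (p >= 0) {
        double f = g_ax[i] / diag[i];
        diag[p] -= g_ax[i] * f;
        rhs[p] += rhs[i] * f;
      }
    }
    // forward pass relies on parent index < child index, so V[p] already
    // holds the updated parent voltage when child i is reached
    for (int i = 0; i < ncomp; ++i) {
      int p = parent[i];
      V[i] = (p >= 0) ? (rhs[i] + g_ax[i] * V[p]) / diag[i]
                      : rhs[i] / diag[i];
    }
    // transmembrane (outward) current per compartment = net axial inflow +
    // injected current; equals capacitive+ionic+synaptic outflow by KCL and
    // sums to the injected total over each cell (axial terms telescope)
    for (int i = 0; i < ncomp; ++i) Imem[i] = Iext[i];
    for (int i = 0; i < ncomp; ++i) {
      int p = parent[i];
      if (p >= 0) {
        double Ia = g_ax[i] * (V[p] - V[i]);
        Imem[i] += Ia; Imem[p] -= Ia;
      }
    }
    if (n_src > 0)
      for (int i = 0; i < ncomp; ++i)
        if (cur_src[i] >= 0) cur_acc[cur_src[i]] += Imem[i];

    // spike detection on somata
    double tnow = t0 + (s + 1) * dt;
    for (int c = 0; c < ncell; ++c) {
      int sc = soma[c];
      double v = V[sc];
      if (!R_finite(v) || std::fabs(v) > 200.0)
        stop("numerical blow-up: |V| > 200 mV in cell %d at t = %.3f ms",
             c + 1, tnow);
      if (v < thresh[c]) {
        armed[c] = 1;
      } else if (armed[c] && tnow - last_spk[c] >= refrac) {
        // upward threshold crossing with refractory latch
        armed[c] = 0;
        last_spk[c] = tnow;
        if (rec_spikes) { spk_t.push_back(tnow); spk_cell.push_back(c + 1); }
        for (int k = cptr[c]; k < cptr[c + 1]; ++k) {
          int at = (int)((s + cdel[k]) % ring);
          queue[at].push_back({ccomp[k] * nslot + cslot[k], cw[k] / syn_norm[cslot[k]]});
        }
      }
    }

    // sampling
    if (sample_every > 0 && ((s + 1) % sample_every == 0)) {
      for (int j = 0; j < vm_comp.size(); ++j) vm_out(samp_i, j) = V[vm_comp[j]];
      if (n_src > 0) {
        for (int j = 0; j < n_src; ++j) {
          cur_out(samp_i, j) = cur_acc[j] / sample_every;
          cur_acc[j] = 0.0;
        }
      }
      ++samp_i;
    }
    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  // final state (for membrane_step-style stepping)
  List state = List::create(
      _["V"] = NumericVector(V.begin(), V.end()),
      _["m"] = NumericVector(m.begin(), m.end()),
      _["h"] = NumericVector(h.begin(), h.end()),
      _["n"] = NumericVector(n.begin(), n.end()),
      _["mkm"] = NumericVector(mkm.begin(), mkm.end()),
      _["qh"] = NumericVector(qh.begin(), qh.end()),
      _["xr"] = NumericVector(xr.begin(), xr.end()),
      _["xd"] = NumericVector(xd.begin(), xd.end()),
      _["last_spike"] = NumericVector(last_spk.begin(), last_spk.end()));

  return List::create(
      _["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
      _["spike_cell"] = IntegerVector(spk_cell.begin(), spk_cell.end()),
      _["vm"] = vm_out, _["currents"] = cur_out, _["state"] = state,
      _["t_end"] = t0 + n_steps * dt);
}
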