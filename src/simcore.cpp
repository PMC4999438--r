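// Core integrator for the conductance-based E/I network.
//
// All unit conventions are fixed here and mirrored on the R side:
//   voltage mV, time ms, conductance nS, capacitance pF, current pA.
// Populations are homogeneous within a class, so compartment/channel
// parameters are passed once per class ("template") and state is laid out
// as [cell][compartment] with a per-class compartment count.
//
// Synapses are dual-exponential conductances aggregated per (pathway, post
// cell): two state variables (rise A, decay B) suffice because every synapse
// in a pathway shares tau1/tau2. Spike propagation uses per-pathway ring
// buffers of conductance increments (uniform delay per pathway).
//
// Gating kinetics: RTM (reduced Traub-Miles) Na/K_dr for the excitatory
// class, Wang-Buzsaki for the fast-spiking inhibitory class, plus a
// high-threshold Ca current, a calcium-gated K_AHP and an optional slow K_M
// on any compartment. Gate updates are exact exponential relaxations using
// voltage-indexed lookup tables of x_inf(V) and exp(-dt/tau_x(V)).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

const double V_TAB_MIN = -130.0, V_TAB_MAX = 70.0, V_TAB_STEP = 0.05;
const int N_TAB = (int)((V_TAB_MAX - V_TAB_MIN) / V_TAB_STEP) + 1;

inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity at x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

// RTM excitatory kinetics (rates in 1/ms, V in mV)
inline double rtm_am(double V) { return 0.32 * vtrap(V + 54.0, 4.0); }
inline double rtm_bm(double V) { return 0.28 * vtrap(-(V + 27.0), 5.0); }
inline double rtm_ah(double V) { return 0.128 * std::exp(-(V + 50.0) / 18.0); }
inline double rtm_bh(double V) { return 4.0 / (1.0 + std::exp(-(V + 27.0) / 5.0)); }
inline double rtm_an(double V) { return 0.032 * vtrap(V + 52.0, 5.0); }
inline double rtm_bn(double V) { return 0.5 * std::exp(-(V + 57.0) / 40.0); }

// Wang-Buzsaki fast-spiking kinetics, phi = 5; m treated as instantaneous
inline double wb_am(double V) { return 0.1 * vtrap(V + 35.0, 10.0); }
inline double wb_bm(double V) { return 4.0 * std::exp(-(V + 60.0) / 18.0); }
inline double wb_ah(double V) { return 5.0 * 0.07 * std::exp(-(V + 58.0) / 20.0); }
inline double wb_bh(double V) { return 5.0 * 1.0 / (std::exp(-0.1 * (V + 28.0)) + 1.0); }
inline double wb_an(double V) { return 5.0 * 0.01 * vtrap(V + 34.0, 10.0); }
inline double wb_bn(double V) { return 5.0 * 0.125 * std::exp(-(V + 44.0) / 80.0); }

// High-threshold Ca activation (first order, tau 1 ms)
inline double ca_sinf(double V) { return 1.0 / (1.0 + std::exp(-(V + 25.0) / 5.0)); }
// Slow K_M gate (first order, tau 100 ms)
inline double km_winf(double V) { return 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0)); }

struct GateTab {
  // x_inf and exp(-dt/tau) per tabulated voltage
  std::vector<double> xinf, fac;
  GateTab() : xinf(N_TAB), fac(N_TAB) {}
  void build(double (*alpha)(double), double (*beta)(double), double dt) {
    for (int i = 0; i < N_TAB; ++i) {
      double V = V_TAB_MIN + i * V_TAB_STEP;
      double a = alpha(V), b = beta(V), s = a + b;
      xinf[i] = a / s;
      fac[i] = std::exp(-dt * s);
    }
  }
  void build_inf_tau(double (*inf)(double), double tau, double dt) {
    double f = std::exp(-dt / tau);
    for (int i = 0; i < N_TAB; ++i) {
      xinf[i] = inf(V_TAB_MIN + i * V_TAB_STEP);
      fac[i] = f;
    }
  }
  inline void step(double V, double &x) const {
    double u = (V - V_TAB_MIN) / V_TAB_STEP;
    int i = (int)u;
    if (i < 0) i = 0;
    if (i >= N_TAB - 1) i = N_TAB - 2;
    double w = u - i;
    if (w < 0) w = 0; if (w > 1) w = 1;
    double xi = xinf[i] + w * (xinf[i + 1] - xinf[i]);
    double fc = fac[i] + w * (fac[i + 1] - fac[i]);
    x = xi + (x - xi) * fc;
  }
  inline double inf_at(double V) const {
    double u = (V - V_TAB_MIN) / V_TAB_STEP;
    int i = (int)u;
    if (i < 0) i = 0;
    if (i >= N_TAB - 1) i = N_TAB - 2;
    double w = u - i;
    return xinf[i] + w * (xinf[i + 1] - xinf[i]);
  }
};

struct ClassTemplate {
  int ncomp;
  std::vector<double> C, gL, EL, gax, gna, gkdr, gca, gkahp, gkm;
  std::vector<int> parent;
  int kin;              // 0 RTM, 1 WB
  double thresh, refract;
};

struct Pathway {
  // recurrent: CSR over presynaptic cells; external: events per source
  bool external;
  double tau1, tau2, erev, delay;
  int target_comp;
  bool eeg;
  double norm;          // peak-normalization of the dual exponential
  // recurrent storage
  std::vector<int> csr_ptr, csr_post;
  std::vector<double> csr_w;
  // external storage
  std::vector<std::vector<double>> ev_times;
  std::vector<std::vector<int>> ev_targets;
  std::vector<std::vector<double>> ev_w;
  std::vector<size_t> ev_cursor;
  // state
  std::vector<double> A, B;           // per post cell
  std::vector<double> ring;           // (delay_steps+1) x ncell increments
  int ring_len = 1;
  double dec1, dec2;                  // per-step decay factors
};

double dualexp_norm(double tau1, double tau2) {
  double tp = tau1 * tau2 / (tau2 - tau1) * std::log(tau2 / tau1);
  return 1.0 / (std::exp(-tp / tau2) - std::exp(-tp / tau1));
}

} // namespace

// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(IntegerVector cell_class, List templates, List pathways,
                     List config) {
  const int ncell = cell_class.size();
  const double dt = as<double>(config["dt"]);
  const double duration = as<double>(config["duration"]);
  const double eeg_dt = as<double>(config["eeg_dt"]);
  const int integrator = as<int>(config["integrator"]); // 0 CN, 1 exp Euler
  NumericVector i_inject = config["i_inject"];          // pA at soma, per cell
  IntegerVector record_v = config["record_v"];          // cell ids (0-based)
  const long nstep = (long)std::llround(duration / dt);
  const int steps_per_samp = std::max(1, (int)std::llround(eeg_dt / dt));
  const long nsamp = nstep / steps_per_samp;

  // ---- class templates ----
  std::vector<ClassTemplate> tmpl(templates.size());
  int maxcomp = 1;
  for (int c = 0; c < (int)templates.size(); ++c) {
    List t = templates[c];
    ClassTemplate &T = tmpl[c];
    T.C = as<std::vector<double>>(t["C"]);
    T.gL = as<std::vector<double>>(t["gL"]);
    T.EL = as<std::vector<double>>(t["EL"]);
    T.gax = as<std::vector<double>>(t["gax"]);
    T.gna = as<std::vector<double>>(t["gna"]);
    T.gkdr = as<std::vector<double>>(t["gkdr"]);
    T.gca = as<std::vector<double>>(t["gca"]);
    T.gkahp = as<std::vector<double>>(t["gkahp"]);
    T.gkm = as<std::vector<double>>(t["gkm"]);
    T.parent = as<std::vector<int>>(t["parent"]);
    T.kin = as<int>(t["kin"]);
    T.thresh = as<double>(t["thresh"]);
    T.refract = as<double>(t["refract"]);
    T.ncomp = (int)T.C.size();
    if (T.ncomp > maxcomp) maxcomp = T.ncomp;
  }

  // gating tables (per kinetics type, for this dt)
  GateTab tab_m[2], tab_h[2], tab_n[2], tab_s, tab_w;
  tab_m[0].build(rtm_am, rtm_bm, dt);
  tab_h[0].build(rtm_ah, rtm_bh, dt);
  tab_n[0].build(rtm_an, rtm_bn, dt);
  tab_m[1].build(wb_am, wb_bm, dt); // used only for m_inf (instantaneous m)
  tab_h[1].build(wb_ah, wb_bh, dt);
  tab_n[1].build(wb_an, wb_bn, dt);
  tab_s.build_inf_tau(ca_sinf, 1.0, dt);
  tab_w.build_inf_tau(km_winf, 100.0, dt);

  const double E_Na = 50.0, E_K = -100.0, E_Ca = 120.0;
  const double ca_scale = 0.002; // [Ca] a.u. per pA of Ca current per ms
  const double ca_tau = 80.0, ca_kd = 0.5;

  // ---- state ----
  std::vector<double> V((size_t)ncell * maxcomp), gm_h(ncell), gm_n(ncell),
      gm_m(ncell), gate_s(ncell), gate_w(ncell), ca(ncell, 0.0),
      last_spike(ncell, -1e9), v_above(ncell, 0.0);
  for (int i = 0; i < ncell; ++i) {
    const ClassTemplate &T = tmpl[cell_class[i]];
    for (int k = 0; k < T.ncomp; ++k) V[(size_t)i * maxcomp + k] = T.EL[k];
    double V0 = T.EL[0];
    gm_m[i] = tab_m[T.kin].inf_at(V0);
    gm_h[i] = tab_h[T.kin].inf_at(V0);
    gm_n[i] = tab_n[T.kin].inf_at(V0);
    gate_s[i] = tab_s.inf_at(V0);
    gate_w[i] = tab_w.inf_at(V0);
  }

  // ---- pathways ----
  std::vector<Pathway> pw(pathways.size());
  for (int p = 0; p < (int)pathways.size(); ++p) {
    List pl = pathways[p];
    Pathway &P = pw[p];
    P.external = as<bool>(pl["external"]);
    P.tau1 = as<double>(pl["tau1"]);
    P.tau2 = as<double>(pl["tau2"]);
    if (P.tau2 <= P.tau1) P.tau2 = P.tau1 * 1.0001; // alpha-function limit
    P.erev = as<double>(pl["erev"]);
    P.delay = as<double>(pl["delay"]);
    P.target_comp = as<int>(pl["target_comp"]);
    P.eeg = as<bool>(pl["eeg"]);
    P.norm = dualexp_norm(P.tau1, P.tau2);
    P.dec1 = std::exp(-dt / P.tau1);
    P.dec2 = std::exp(-dt / P.tau2);
    P.A.assign(ncell, 0.0);
    P.B.assign(ncell, 0.0);
    int dsteps = (int)std::llround(P.delay / dt);
    P.ring_len = dsteps + 1;
    if (P.external) {
      List ev = pl["events"], tg = pl["targets"], wl = pl["weights"];
      int ns = ev.size();
      P.ev_times.resize(ns);
      P.ev_targets.resize(ns);
      P.ev_w.resize(ns);
      P.ev_cursor.assign(ns, 0);
      for (int s = 0; s < ns; ++s) {
        P.ev_times[s] = as<std::vector<double>>(ev[s]);
        P.ev_targets[s] = as<std::vector<int>>(tg[s]);
        P.ev_w[s] = as<std::vector<double>>(wl[s]);
      }
    } else {
      IntegerVector pre = pl["pre"], post = pl["post"];
      NumericVector w = pl["w"];
      // CSR over presynaptic id
      P.csr_ptr.assign(ncell + 1, 0);
      for (int e = 0; e < pre.size(); ++e) P.csr_ptr[pre[e] + 1]++;
      for (int i = 0; i < ncell; ++i) P.csr_ptr[i + 1] += P.csr_ptr[i];
      P.csr_post.resize(pre.size());
      P.csr_w.resize(pre.size());
      std::vector<int> fill(P.csr_ptr.begin(), P.csr_ptr.end() - 1);
      for (int e = 0; e < pre.size(); ++e) {
        int slot = fill[pre[e]]++;
        P.csr_post[slot] = post[e];
        P.csr_w[slot] = w[e];
      }
    }
    P.ring.assign((size_t)P.ring_len * ncell, 0.0);
  }

  // per-cell per-comp synaptic accumulators, rebuilt each step
  std::vector<double> syn_g((size_t)ncell * maxcomp), syn_ge((size_t)ncell * maxcomp);

  std::vector<int> spike_cell;
  std::vector<double> spike_time;
  spike_cell.reserve(1 << 16);
  spike_time.reserve(1 << 16);

  NumericVector eeg(nsamp);
  // per-pathway EEG components (for diagnostics/decomposition)
  NumericMatrix eeg_comp(nsamp, (int)pw.size());
  std::vector<double> comp_acc(pw.size(), 0.0);
  NumericMatrix vrec(record_v.size() > 0 ? nsamp : 0, record_v.size());
  double eeg_acc = 0.0;
  int samp_ctr = 0;
  long samp_idx = 0;
  bool bad = false;
  long bad_step = -1;
  int bad_cell = -1;

  for (long s = 0; s < nstep && !bad; ++s) {
    double t = s * dt;
    // deliver ring-buffer increments and external events
    for (auto &P : pw) {
      int slot = (int)(s % P.ring_len);
      double *ring0 = &P.ring[(size_t)slot * ncell];
      for (int i = 0; i < ncell; ++i) {
        double inc = ring0[i];
        if (inc != 0.0) {
          P.A[i] += inc;
          P.B[i] += inc;
          ring0[i] = 0.0;
        }
      }
      if (P.external) {
        int dsteps = P.ring_len - 1;
        for (size_t src = 0; src < P.ev_times.size(); ++src) {
          auto &tv = P.ev_times[src];
          size_t &cur = P.ev_cursor[src];
          while (cur < tv.size() && tv[cur] < t + dt) {
            const auto &tg = P.ev_targets[src];
            const auto &wv = P.ev_w[src];
            if (dsteps == 0) {
              for (size_t k = 0; k < tg.size(); ++k) {
                double inc = wv[k] * P.norm;
                P.A[tg[k]] += inc;
                P.B[tg[k]] += inc;
              }
            } else {
              int slot2 = (int)((s + dsteps) % P.ring_len);
              double *r2 = &P.ring[(size_t)slot2 * ncell];
              for (size_t k = 0; k < tg.size(); ++k) r2[tg[k]] += wv[k] * P.norm;
            }
            ++cur;
          }
        }
      }
    }

    // synaptic conductance accumulation
    std::fill(syn_g.begin(), syn_g.end(), 0.0);
    std::fill(syn_ge.begin(), syn_ge.end(), 0.0);
    for (size_t pi = 0; pi < pw.size(); ++pi) {
      Pathway &P = pw[pi];
      int tc = P.target_comp;
      double acc = 0.0;
      for (int i = 0; i < ncell; ++i) {
        double g = P.B[i] - P.A[i];
        if (g > 1e-12) {
          size_t idx = (size_t)i * maxcomp + tc;
          syn_g[idx] += g;
          syn_ge[idx] += g * P.erev;
          if (P.eeg) acc += g * (P.erev - V[idx]);
        }
      }
      comp_acc[pi] += acc;
      eeg_acc += acc;
    }

    // membrane update
    for (int i = 0; i < ncell; ++i) {
      const ClassTemplate &T = tmpl[cell_class[i]];
      double *Vi = &V[(size_t)i * maxcomp];
      double Vs = Vi[0];
      // gates (soma voltage governs spiking channels)
      if (T.kin == 0) {
        tab_m[0].step(Vs, gm_m[i]);
      } else {
        gm_m[i] = tab_m[1].inf_at(Vs); // WB: instantaneous activation
      }
      tab_h[T.kin].step(Vs, gm_h[i]);
      tab_n[T.kin].step(Vs, gm_n[i]);
      tab_s.step(Vs, gate_s[i]);
      tab_w.step(Vs, gate_w[i]);

      double newV[8];
      double i_ca_soma = 0.0;
      for (int k = 0; k < T.ncomp; ++k) {
        double Vk = Vi[k];
        double gtot = T.gL[k] + syn_g[(size_t)i * maxcomp + k];
        double num = T.gL[k] * T.EL[k] + syn_ge[(size_t)i * maxcomp + k];
        if (k == 0) num += i_inject[i];
        // active channels (gates driven by soma voltage; conductances per comp)
        if (T.gna[k] > 0) {
          double m = gm_m[i], g = T.gna[k] * m * m * m * gm_h[i];
          gtot += g; num += g * E_Na;
        }
        if (T.gkdr[k] > 0) {
          double n = gm_n[i], g = T.gkdr[k] * n * n * n * n;
          gtot += g; num += g * E_K;
        }
        if (T.gca[k] > 0) {
          double ss = gate_s[i], g = T.gca[k] * ss * ss;
          gtot += g; num += g * E_Ca;
          i_ca_soma += g * (Vk - E_Ca);
        }
        if (T.gkahp[k] > 0) {
          double g = T.gkahp[k] * (ca[i] / (ca[i] + ca_kd));
          gtot += g; num += g * E_K;
        }
        if (T.gkm[k] > 0) {
          double g = T.gkm[k] * gate_w[i];
          gtot += g; num += g * E_K;
        }
        // axial coupling (explicit neighbor voltages)
        int par = T.parent[k];
        if (par >= 0) {
          gtot += T.gax[k];
          num += T.gax[k] * Vi[par];
        }
        for (int k2 = 0; k2 < T.ncomp; ++k2)
          if (T.parent[k2] == k) {
            gtot += T.gax[k2];
            num += T.gax[k2] * Vi[k2];
          }
        double a = dt / T.C[k];
        if (integrator == 1) {
          double vinf = num / gtot;
          newV[k] = vinf + (Vk - vinf) * std::exp(-a * gtot);
        } else {
          // semi-implicit trapezoid (Crank-Nicolson on the voltage equation)
          newV[k] = (Vk * (1.0 - 0.5 * a * gtot) + a * num) / (1.0 + 0.5 * a * gtot);
        }
      }
      for (int k = 0; k < T.ncomp; ++k) Vi[k] = newV[k];
      // calcium pool (driven by somatic Ca current; inward current is negative)
      ca[i] += dt * (-ca_scale * i_ca_soma - ca[i] / ca_tau);
      if (ca[i] < 0) ca[i] = 0;

      if (!std::isfinite(Vi[0]) || Vi[0] > 200.0 || Vi[0] < -300.0) {
        bad = true; bad_step = s; bad_cell = i;
        break;
      }
      // spike detection: upward threshold crossing + refractory lockout
      if (Vi[0] >= T.thresh) {
        if (v_above[i] == 0.0 && (t - last_spike[i]) >= T.refract) {
          last_spike[i] = t;
          spike_cell.push_back(i);
          spike_time.push_back(t);
          // propagate through recurrent pathways
          for (auto &P : pw) {
            if (P.external || P.csr_ptr.empty()) continue;
            int b = P.csr_ptr[i], e = P.csr_ptr[i + 1];
            if (b == e) continue;
            int slot2 = (int)((s + P.ring_len - 1) % P.ring_len);
            double *r2 = &P.ring[(size_t)slot2 * ncell];
            for (int j = b; j < e; ++j) r2[P.csr_post[j]] += P.csr_w[j] * P.norm;
          }
        }
        v_above[i] = 1.0;
      } else {
        v_above[i] = 0.0;
      }
    }

    // synaptic decay
    for (auto &P : pw)
      for (int i = 0; i < ncell; ++i) {
        P.A[i] *= P.dec1;
        P.B[i] *= P.dec2;
      }

    // EEG / voltage sampling (bin average for EEG, instantaneous for V)
    if (++samp_ctr == steps_per_samp) {
      if (samp_idx < nsamp) {
        eeg[samp_idx] = eeg_acc / steps_per_samp;
        for (size_t pi = 0; pi < pw.size(); ++pi)
          eeg_comp(samp_idx, (int)pi) = comp_acc[pi] / steps_per_samp;
        for (int r = 0; r < record_v.size(); ++r)
          vrec(samp_idx, r) = V[(size_t)record_v[r] * maxcomp];
      }
      eeg_acc = 0.0;
      std::fill(comp_acc.begin(), comp_acc.end(), 0.0);
      samp_ctr = 0;
      ++samp_idx;
    }
  }

  if (bad)
    stop("integration failure (non-finite or divergent voltage) at t = %f ms in cell %d",
         bad_step * dt, bad_cell + 1);

  return List::create(_["spike_cell"] = wrap(spike_cell),
                      _["spike_time"] = wrap(spike_time),
                      _["eeg"] = eeg, _["eeg_dt"] = eeg_dt,
                      _["eeg_components"] = eeg_comp, _["v"] = vrec);
}
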