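// Clock-driven core for the three-population (P, B, A) conductance-based
// LIF network: exponential-Euler conductance decay, forward-Euler membrane
// update, per-synapse-type delay ring buffers, presynaptic short-term
// depression/facilitation, and read-only "clone" neurons used to measure
// state-dependent f-I curves without perturbing the recurrent network.
//
// Units: mV, ms, pA, nS, pF throughout (dt/C has units mV/pA).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// Portable counter-free RNG: splitmix64-seeded xoshiro256++.  Used instead of
// R's RNG so that connectivity sampling is bit-reproducible regardless of the
// caller's RNG state, and uniform doubles are generated by an explicit
// bit-shift mapping (no implementation-defined std::distribution).
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1): 53-bit mantissa, zero excluded for safe log()
  double unif() {
    uint64_t u = next() >> 11;
    return (static_cast<double>(u) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct RingEntry {
  int type;      // synapse type, pre*3 + post
  int pre;       // presynaptic neuron index within its population
  double factor; // efficacy scaling frozen at spike time
};

inline int pop_of_type_pre(int t) { return t / 3; }
inline int pop_of_type_post(int t) { return t % 3; }

} // namespace

// Bernoulli(p) sampling of directed edges pre -> post by geometric gap
// skipping; self-edges excluded when same_pop.  Returns CSR offsets/targets.
// [[Rcpp::export(name = ".cpp_sample_adjacency")]]
List cpp_sample_adjacency(int n_pre, int n_post, double p, bool same_pop,
                          double seed) {
  std::vector<int> offsets(n_pre + 1, 0);
  std::vector<int> targets;
  if (p > 0.0 && n_post > 0) {
    Xoshiro rng(static_cast<uint64_t>(seed));
    targets.reserve(static_cast<size_t>(
        std::min(1.05 * n_pre * n_post * p + 64.0, 4e9)));
    const double log1mp = (p < 1.0) ? std::log1p(-p) : 0.0;
    for (int j = 0; j < n_pre; ++j) {
      if (p >= 1.0) {
        for (int i = 0; i < n_post; ++i)
          if (!(same_pop && i == j)) targets.push_back(i);
      } else {
        long long pos = -1;
        while (true) {
          double u = rng.unif();
          pos += 1 + static_cast<long long>(std::floor(std::log(u) / log1mp));
          if (pos >= n_post) break;
          if (!(same_pop && pos == j)) targets.push_back(static_cast<int>(pos));
        }
      }
      offsets[j + 1] = static_cast<int>(targets.size());
    }
  }
  return List::create(_["offsets"] = wrap(offsets), _["targets"] = wrap(targets));
}

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List net, List run) {
  // ---- unpack network ----
  IntegerVector n = net["n"];
  NumericVector Cm = net["C"], gL = net["g_L"], Vrest = net["V_rest"],
                Vthr = net["V_thr"], Vreset = net["V_reset"],
                trefr = net["t_refr"];
  NumericVector Erev = net["E_rev"];       // by presynaptic population
  NumericVector tau_syn = net["tau_syn"];  // by presynaptic population
  NumericVector g_unit = net["g_unit"], delay_ms = net["delay"];
  List adj = net["adj"];
  LogicalVector dep_on = net["dep_on"];
  NumericVector dep_eta = net["dep_eta"], dep_tau = net["dep_tau"];
  LogicalVector fac_on = net["fac_on"];
  NumericVector fac_eta = net["fac_eta"], fac_tau = net["fac_tau"],
                fac_zmax = net["fac_zmax"], fac_scale = net["fac_scale"],
                fac_zinit = net["fac_zinit"];
  LogicalVector clamp_on = net["clamp_on"];
  NumericVector clamp_val = net["clamp_val"];
  double I_BG = as<double>(net["I_BG"]);

  // ---- unpack run options ----
  const double dt = as<double>(run["dt"]);
  const double duration = as<double>(run["duration"]);
  const int n_steps = static_cast<int>(std::llround(duration / dt));
  const int record_every = as<int>(run["record_every"]);
  const double transient_ms = as<double>(run["transient_ms"]);
  const int transient_steps = static_cast<int>(std::llround(transient_ms / dt));
  List init_V = run["init_V"];
  List stim = run["stim"];
  List rec_spikes = run["rec_spikes"];
  List rec_Vm = run["rec_Vm"];

  // ---- per-population state ----
  std::vector<std::vector<double>> V(3), Iext(3);
  std::vector<std::vector<double>> g(9); // g[type][post index]: conductance of
                                         // type 'type' onto each post neuron
  std::vector<std::vector<int>> refr(3);
  std::vector<int> refr_steps(3);
  for (int p = 0; p < 3; ++p) {
    NumericVector v0 = init_V[p];
    if (v0.size() != n[p]) stop("init_V length mismatch");
    V[p].assign(v0.begin(), v0.end());
    Iext[p].assign(n[p], 0.0);
    refr[p].assign(n[p], 0);
    refr_steps[p] = static_cast<int>(std::llround(trefr[p] / dt));
  }
  NumericVector init_g = run["init_g"]; // per-type initial conductance (nS)
  for (int t = 0; t < 9; ++t)
    g[t].assign(n[pop_of_type_post(t)], init_g[t]);

  // adjacency CSR views
  std::vector<const int*> adj_off(9), adj_tgt(9);
  std::vector<int> adj_ntgt(9);
  std::vector<IntegerVector> adj_off_keep(9), adj_tgt_keep(9);
  for (int t = 0; t < 9; ++t) {
    List a = adj[t];
    adj_off_keep[t] = a["offsets"];
    adj_tgt_keep[t] = a["targets"];
    adj_off[t] = adj_off_keep[t].begin();
    adj_tgt[t] = adj_tgt_keep[t].begin();
    adj_ntgt[t] = adj_tgt_keep[t].size();
  }

  // plasticity state per (type, presynaptic neuron)
  std::vector<std::vector<double>> eff(9), zf(9);
  std::vector<double> dep_decay(9, 1.0), fac_decay(9, 1.0);
  for (int t = 0; t < 9; ++t) {
    int npre = n[pop_of_type_pre(t)];
    if (dep_on[t]) {
      eff[t].assign(npre, 1.0);
      dep_decay[t] = std::exp(-dt / dep_tau[t]);
    }
    if (fac_on[t]) {
      zf[t].assign(npre, fac_zinit[t]);
      fac_decay[t] = std::exp(-dt / fac_tau[t]);
    }
  }

  // conductance decay factors by presynaptic population
  double g_decay[3];
  for (int p = 0; p < 3; ++p) g_decay[p] = std::exp(-dt / tau_syn[p]);

  // charge-conserving delta delivery: the discrete conductance pulse
  // (held constant within each step, exact exponential decay between steps)
  // carries total area g_unit * dt / (1 - exp(-dt/tau)); scale the jump so
  // the area equals the continuous-time value g_unit * tau at any dt
  double g_charge[3];
  for (int p = 0; p < 3; ++p)
    g_charge[p] = tau_syn[p] * (1.0 - g_decay[p]) / dt;
  std::vector<double> g_jump(9);
  for (int t = 0; t < 9; ++t)
    g_jump[t] = g_unit[t] * g_charge[pop_of_type_pre(t)];

  // ---- delay ring buffer ----
  std::vector<int> delay_steps(9);
  int ring_len = 2;
  for (int t = 0; t < 9; ++t) {
    delay_steps[t] = static_cast<int>(std::llround(delay_ms[t] / dt));
    if (std::fabs(delay_steps[t] * dt - delay_ms[t]) > 1e-9)
      stop("synaptic delay must be an integer multiple of dt");
    if (delay_steps[t] < 1) stop("synaptic delay must be at least one step");
    ring_len = std::max(ring_len, delay_steps[t] + 2);
  }
  std::vector<std::vector<RingEntry>> ring(ring_len);

  // ---- stimuli: expand to activation/deactivation event lists ----
  struct StimEvent { int step; int pop; const int* idx; const double* amp; int k; double sign; };
  std::vector<StimEvent> events;
  std::vector<IntegerVector> stim_idx_keep;
  std::vector<NumericVector> stim_amp_keep;
  stim_idx_keep.reserve(stim.size());
  stim_amp_keep.reserve(stim.size());
  for (int si = 0; si < stim.size(); ++si) {
    List s = stim[si];
    stim_idx_keep.push_back(as<IntegerVector>(s["idx"]));
    stim_amp_keep.push_back(as<NumericVector>(s["amp"]));
    const IntegerVector& ix = stim_idx_keep.back();
    const NumericVector& am = stim_amp_keep.back();
    if (ix.size() != am.size()) stop("stimulus idx/amp length mismatch");
    int on = static_cast<int>(std::llround(as<double>(s["on_ms"]) / dt));
    int off = on + static_cast<int>(std::llround(as<double>(s["duration_ms"]) / dt));
    int pop = as<int>(s["pop"]);
    events.push_back({on, pop, ix.begin(), am.begin(), static_cast<int>(ix.size()), +1.0});
    events.push_back({off, pop, ix.begin(), am.begin(), static_cast<int>(ix.size()), -1.0});
  }
  std::sort(events.begin(), events.end(),
            [](const StimEvent& a, const StimEvent& b) { return a.step < b.step; });
  size_t next_event = 0;

  // ---- clones (read-only copies; never feed back) ----
  bool have_clones = run.containsElementNamed("clones") &&
                     !Rf_isNull(run["clones"]);
  int n_clones = 0;
  std::vector<int> clone_pop;
  std::vector<double> clone_Iext, clone_V;
  std::vector<int> clone_refr;
  std::vector<std::vector<double>> clone_g(3); // by presynaptic population
  std::vector<const int*> cadj_off(9, nullptr), cadj_tgt(9, nullptr);
  std::vector<int> cadj_ntgt(9, 0);
  std::vector<IntegerVector> cadj_off_keep(9), cadj_tgt_keep(9);
  std::vector<double> clone_cur_sum, clone_cur_sumsq;
  std::vector<int> clone_spikes;
  long long clone_acc_n = 0;
  if (have_clones) {
    List cl = run["clones"];
    IntegerVector cp = cl["pop"];
    NumericVector ci = cl["Iext"];
    n_clones = cp.size();
    clone_pop.assign(cp.begin(), cp.end());
    clone_Iext.assign(ci.begin(), ci.end());
    clone_V.resize(n_clones);
    for (int c = 0; c < n_clones; ++c) clone_V[c] = Vrest[clone_pop[c]];
    clone_refr.assign(n_clones, 0);
    for (int p = 0; p < 3; ++p) clone_g[p].assign(n_clones, 0.0);
    List ca = cl["adj"];
    for (int t = 0; t < 9; ++t) {
      List a = ca[t];
      cadj_off_keep[t] = as<IntegerVector>(a["offsets"]);
      cadj_tgt_keep[t] = as<IntegerVector>(a["targets"]);
      cadj_off[t] = cadj_off_keep[t].begin();
      cadj_tgt[t] = cadj_tgt_keep[t].begin();
      cadj_ntgt[t] = cadj_tgt_keep[t].size();
    }
    clone_cur_sum.assign(n_clones, 0.0);
    clone_cur_sumsq.assign(n_clones, 0.0);
    clone_spikes.assign(n_clones, 0);
  }

  // ---- recording ----
  const int n_samples = n_steps / record_every + 1;
  NumericVector t_out(n_samples);
  NumericMatrix counts(n_samples, 3);        // spikes per record bin
  NumericMatrix curr_P(n_samples, 3);        // mean input current onto P cells
  NumericVector eAB_tr(n_samples), ePB_tr(n_samples), zAP_tr(n_samples);
  const int T_AB = 1 * 3 + 2, T_PB = 1 * 3 + 0, T_AP = 0 * 3 + 2; // pre*3+post

  std::vector<std::vector<char>> rec_spk_flag(3);
  std::vector<std::vector<double>> spk_t(3);
  std::vector<std::vector<int>> spk_i(3);
  for (int p = 0; p < 3; ++p) {
    rec_spk_flag[p].assign(n[p], 0);
    IntegerVector ids = rec_spikes[p];
    for (int k = 0; k < ids.size(); ++k) rec_spk_flag[p][ids[k]] = 1;
  }
  std::vector<IntegerVector> vm_ids(3);
  std::vector<NumericMatrix> vm_out(3);
  for (int p = 0; p < 3; ++p) {
    vm_ids[p] = as<IntegerVector>(rec_Vm[p]);
    vm_out[p] = NumericMatrix(n_samples, vm_ids[p].size());
  }

  // out-degree weights for synapse-averaged efficacy traces
  auto wmean = [&](int t, const std::vector<double>& x) -> double {
    if (x.empty()) return NA_REAL;
    double num = 0.0, den = 0.0;
    int npre = n[pop_of_type_pre(t)];
    for (int j = 0; j < npre; ++j) {
      double d = static_cast<double>(adj_off[t][j + 1] - adj_off[t][j]);
      num += d * x[j]; den += d;
    }
    if (den == 0.0) { // no realized synapses: plain mean
      for (int j = 0; j < npre; ++j) num += x[j];
      return num / npre;
    }
    return num / den;
  };

  double bin_count[3] = {0.0, 0.0, 0.0};

  auto take_sample = [&](int k, int step) {
    t_out[k] = step * dt;
    for (int p = 0; p < 3; ++p) { counts(k, p) = bin_count[p]; bin_count[p] = 0.0; }
    // mean input current from each presynaptic population onto P cells,
    // I = -g (V - E): excitatory positive, inhibitory negative
    for (int pre = 0; pre < 3; ++pre) {
      int t = pre * 3 + 0;
      double acc = 0.0;
      const std::vector<double>& gt = g[t];
      for (int i = 0; i < n[0]; ++i) acc -= gt[i] * (V[0][i] - Erev[pre]);
      curr_P(k, pre) = acc / n[0];
    }
    eAB_tr[k] = clamp_on[T_AB] ? clamp_val[T_AB]
               : (dep_on[T_AB] ? wmean(T_AB, eff[T_AB]) : 1.0);
    ePB_tr[k] = clamp_on[T_PB] ? clamp_val[T_PB]
               : (dep_on[T_PB] ? wmean(T_PB, eff[T_PB]) : 1.0);
    zAP_tr[k] = fac_on[T_AP] ? wmean(T_AP, zf[T_AP]) : 0.0;
    for (int p = 0; p < 3; ++p)
      for (int c = 0; c < vm_ids[p].size(); ++c)
        vm_out[p](k, c) = V[p][vm_ids[p][c]];
  };

  take_sample(0, 0);
  int sample_k = 1;

  std::vector<int> fired_idx; fired_idx.reserve(4096);

  // ---- main loop ----
  for (int s = 0; s < n_steps; ++s) {
    // stimulus on/off events at this step
    while (next_event < events.size() && events[next_event].step <= s) {
      const StimEvent& ev = events[next_event];
      for (int k = 0; k < ev.k; ++k) Iext[ev.pop][ev.idx[k]] += ev.sign * ev.amp[k];
      ++next_event;
    }

    // exact exponential conductance decay
    for (int t = 0; t < 9; ++t) {
      double d = g_decay[pop_of_type_pre(t)];
      std::vector<double>& gt = g[t];
      for (size_t i = 0; i < gt.size(); ++i) gt[i] *= d;
    }
    if (have_clones)
      for (int p = 0; p < 3; ++p) {
        double d = g_decay[p];
        for (int c = 0; c < n_clones; ++c) clone_g[p][c] *= d;
      }

    // deliver spikes whose delay elapses now
    std::vector<RingEntry>& slot = ring[s % ring_len];
    for (const RingEntry& en : slot) {
      const int t = en.type;
      const double inc = g_jump[t] * en.factor;
      std::vector<double>& gt = g[t];
      const int* tgt = adj_tgt[t];
      for (int q = adj_off[t][en.pre]; q < adj_off[t][en.pre + 1]; ++q)
        gt[tgt[q]] += inc;
      if (have_clones && cadj_ntgt[t] > 0) {
        std::vector<double>& gc = clone_g[pop_of_type_pre(t)];
        const int* ct = cadj_tgt[t];
        for (int q = cadj_off[t][en.pre]; q < cadj_off[t][en.pre + 1]; ++q)
          gc[ct[q]] += inc;
      }
    }
    slot.clear();

    // plasticity relaxation (between-spike dynamics)
    for (int t = 0; t < 9; ++t) {
      if (dep_on[t] && !clamp_on[t]) {
        double d = dep_decay[t];
        std::vector<double>& e = eff[t];
        for (size_t j = 0; j < e.size(); ++j) e[j] = 1.0 - (1.0 - e[j]) * d;
      }
      if (fac_on[t]) {
        double d = fac_decay[t];
        std::vector<double>& z = zf[t];
        for (size_t j = 0; j < z.size(); ++j) z[j] *= d;
      }
    }

    // membrane update + threshold detection
    for (int p = 0; p < 3; ++p) {
      const double k_dtC = dt / Cm[p];
      const double gl = gL[p], vr = Vrest[p], vt = Vthr[p], vres = Vreset[p];
      std::vector<double>& Vp = V[p];
      std::vector<int>& rf = refr[p];
      const std::vector<double>& gP = g[0 * 3 + p];
      const std::vector<double>& gB = g[1 * 3 + p];
      const std::vector<double>& gA = g[2 * 3 + p];
      fired_idx.clear();
      for (int i = 0; i < n[p]; ++i) {
        if (rf[i] > 0) { --rf[i]; Vp[i] = vres; continue; }
        double v = Vp[i];
        double Isyn = -(gP[i] * (v - Erev[0]) + gB[i] * (v - Erev[1]) +
                        gA[i] * (v - Erev[2]));
        v += k_dtC * (gl * (vr - v) + Isyn + I_BG + Iext[p][i]);
        if (v >= vt) {
          Vp[i] = vres;
          rf[i] = refr_steps[p];
          fired_idx.push_back(i);
        } else {
          Vp[i] = v;
        }
      }
      // register spikes: counts, recording, ring entries, plasticity jumps
      bin_count[p] += static_cast<double>(fired_idx.size());
      const double t_spk = (s + 1) * dt;
      for (int i : fired_idx) {
        if (rec_spk_flag[p][i]) { spk_t[p].push_back(t_spk); spk_i[p].push_back(i); }
        for (int post = 0; post < 3; ++post) {
          const int t = p * 3 + post;
          if (adj_ntgt[t] == 0 && cadj_ntgt[t] == 0) continue;
          double f = 1.0;
          if (clamp_on[t]) f = clamp_val[t];
          else if (dep_on[t]) f = eff[t][i];
          else if (fac_on[t]) f = (1.0 + zf[t][i]) * fac_scale[t];
          // the spike occurs at the end of step s, i.e. time (s+1) dt; its
          // conductance jump is delivered at the start of the step whose
          // time is spike time + delay
          ring[(s + 1 + delay_steps[t]) % ring_len].push_back({t, i, f});
        }
        for (int post = 0; post < 3; ++post) {
          const int t = p * 3 + post;
          if (dep_on[t] && !clamp_on[t]) eff[t][i] *= (1.0 - dep_eta[t]);
          if (fac_on[t]) zf[t][i] += (fac_zmax[t] - zf[t][i]) * fac_eta[t];
        }
      }
    }

    // clones: same membrane dynamics, no feedback into the network
    if (have_clones) {
      const bool acc = (s >= transient_steps);
      for (int c = 0; c < n_clones; ++c) {
        const int p = clone_pop[c];
        double v = clone_V[c];
        const bool in_refr = clone_refr[c] > 0;
        if (in_refr) { --clone_refr[c]; v = Vreset[p]; }
        double Isyn = -(clone_g[0][c] * (v - Erev[0]) +
                        clone_g[1][c] * (v - Erev[1]) +
                        clone_g[2][c] * (v - Erev[2]));
        double Itot = Isyn + I_BG + clone_Iext[c];
        if (acc) { clone_cur_sum[c] += Itot; clone_cur_sumsq[c] += Itot * Itot; }
        if (!in_refr) {
          v += (dt / Cm[p]) * (gL[p] * (Vrest[p] - v) + Isyn + I_BG + clone_Iext[c]);
          if (v >= Vthr[p]) {
            v = Vreset[p];
            clone_refr[c] = refr_steps[p];
            if (acc) ++clone_spikes[c];
          }
        }
        clone_V[c] = v;
      }
      if (acc) ++clone_acc_n;
    }

    if ((s + 1) % record_every == 0 && sample_k < n_samples)
      take_sample(sample_k++, s + 1);

    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();

    // non-finite guard (cheap: first neuron of each population)
    if ((s & 0x3FF) == 0)
      for (int p = 0; p < 3; ++p)
        if (!std::isfinite(V[p][0]))
          stop("non-finite membrane potential at t = %f ms", s * dt);
  }

  List spikes(3);
  for (int p = 0; p < 3; ++p)
    spikes[p] = List::create(_["time"] = wrap(spk_t[p]), _["id"] = wrap(spk_i[p]));

  List out = List::create(
      _["t"] = t_out, _["counts"] = counts, _["curr_P"] = curr_P,
      _["eAB"] = eAB_tr, _["ePB"] = ePB_tr, _["zAP"] = zAP_tr,
      _["spikes"] = spikes,
      _["Vm"] = List::create(vm_out[0], vm_out[1], vm_out[2]));

  if (have_clones) {
    NumericVector cmean(n_clones), csd(n_clones), crate(n_clones);
    const double nacc = static_cast<double>(std::max(clone_acc_n, 1LL));
    const double T_acc = nacc * dt / 1000.0; // seconds of accumulation
    for (int c = 0; c < n_clones; ++c) {
      double m = clone_cur_sum[c] / nacc;
      double v = clone_cur_sumsq[c] / nacc - m * m;
      cmean[c] = m;
      csd[c] = std::sqrt(std::max(v, 0.0));
      crate[c] = clone_spikes[c] / T_acc;
    }
    out["clone_curr_mean"] = cmean;
    out["clone_curr_sd"] = csd;
    out["clone_rate"] = crate;
  }
  return out;
}
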