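#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Clock-driven simulation core for the olivocerebellar network.
//
// All neurons follow the E-GLIF point model:
//   dV/dt      = -(V - E_rest)/tau_m + (I_e + I_dep - I_adap + I_syn)/Cm
//   dI_adap/dt = k_adap (V - E_rest) - k2 I_adap
//   dI_dep/dt  = -k1 I_dep
// integrated with exponential Euler (coupling terms frozen over one dt).
// Spike test at step end; on spike: V -> V_reset, I_dep += A1, I_adap += A2,
// absolute refractory t_ref with V clamped at V_reset.
//
// Synapses are conductance based (one excitatory, one inhibitory exponential
// conductance per neuron); presynaptic spikes add the connection weight to the
// target conductance after the connection delay (delays rounded to the grid).

namespace {

struct Edge {
  int post;      // global target neuron index
  double *w;     // pointer into the group's weight vector
  int delay;     // steps
  int rec;       // 0 = excitatory, 1 = inhibitory
};

// parameter column order (matches R side)
enum Par { CM = 0, TAUM, EREST, VTH, VRESET, TREF, IE, KADAP, K1, K2, A1P, A2P, NPAR };

inline int first_at_or_after(const std::vector<double> &v, double t) {
  return int(std::lower_bound(v.begin(), v.end(), t) - v.begin());
}

} // namespace

// [[Rcpp::export]]
List cpp_run_session(NumericMatrix par, NumericMatrix recpar, NumericMatrix init,
                     List groups, List mf_trains, List inj_trains,
                     int n_trials, double trial_ms, double dt,
                     List plast, int snapshot_every, int warmup_steps) {
  const int N = par.nrow();
  const int n_steps = int(std::lround(trial_ms / dt));

  // --- unpack neuron parameters and precompute per-neuron decay factors
  std::vector<double> Cm(N), Er(N), Vth(N), Vres(N), Tref(N), Ie(N);
  std::vector<double> kad(N), k2(N), A1(N), A2(N);
  std::vector<double> em(N), taum(N), e1(N), e2(N), cad(N), ge_d(N), gi_d(N);
  std::vector<double> Ee(N), Ei(N);
  for (int i = 0; i < N; ++i) {
    Cm[i] = par(i, CM); taum[i] = par(i, TAUM); Er[i] = par(i, EREST);
    Vth[i] = par(i, VTH); Vres[i] = par(i, VRESET); Tref[i] = par(i, TREF);
    Ie[i] = par(i, IE); kad[i] = par(i, KADAP); k2[i] = par(i, K2);
    A1[i] = par(i, A1P); A2[i] = par(i, A2P);
    em[i] = std::exp(-dt / taum[i]);
    e1[i] = std::exp(-par(i, K1) * dt);
    e2[i] = std::exp(-k2[i] * dt);
    cad[i] = (k2[i] > 0) ? (kad[i] / k2[i]) * (1.0 - e2[i]) : kad[i] * dt;
    ge_d[i] = std::exp(-dt / recpar(i, 0));
    gi_d[i] = std::exp(-dt / recpar(i, 1));
    Ee[i] = recpar(i, 2); Ei[i] = recpar(i, 3);
  }

  // --- state
  std::vector<double> V(N), Ia(N), Id(N), refr(N), ge(N, 0.0), gi(N, 0.0);
  for (int i = 0; i < N; ++i) {
    V[i] = init(i, 0); Ia[i] = init(i, 1); Id[i] = init(i, 2); refr[i] = init(i, 3);
  }

  // --- connectivity: adjacency per source (mf ids and global neuron ids)
  const int n_groups = groups.size();
  std::vector<NumericVector> gw(n_groups); // keep weight vectors alive / writable
  int max_delay = 1;
  int plast_group = as<int>(plast["group"]);
  bool plast_on = as<bool>(plast["enabled"]) && plast_group >= 0;

  struct RawGroup { int src_kind; IntegerVector pre, post; int delay, sign; };
  std::vector<RawGroup> rg(n_groups);
  int n_mf = 0;
  for (int g = 0; g < n_groups; ++g) {
    List grp = groups[g];
    rg[g].src_kind = as<int>(grp["src_kind"]);
    rg[g].pre = grp["pre"]; rg[g].post = grp["post"];
    rg[g].delay = as<int>(grp["delay_steps"]); rg[g].sign = as<int>(grp["sign"]);
    gw[g] = clone(as<NumericVector>(grp["w"])); // plasticity must not alias the caller's weights
    max_delay = std::max(max_delay, rg[g].delay);
    if (rg[g].src_kind == 0)
      for (int k = 0; k < rg[g].pre.size(); ++k) n_mf = std::max(n_mf, rg[g].pre[k] + 1);
  }
  std::vector<std::vector<Edge> > mf_adj(n_mf), neu_adj(N);
  for (int g = 0; g < n_groups; ++g) {
    for (int k = 0; k < rg[g].pre.size(); ++k) {
      Edge e; e.post = rg[g].post[k]; e.w = &gw[g][k];
      e.delay = rg[g].delay; e.rec = (rg[g].sign > 0) ? 0 : 1;
      if (rg[g].src_kind == 0) mf_adj[rg[g].pre[k]].push_back(e);
      else neu_adj[rg[g].pre[k]].push_back(e);
    }
  }

  // --- delayed-delivery ring buffer (per step slot, neuron, receptor)
  const int L = max_delay + 1;
  std::vector<double> ring(size_t(L) * N * 2, 0.0);
  long step_abs = 0; // absolute step counter across trials (ring phase)

  // --- plasticity bookkeeping
  double ltp = as<double>(plast["ltp"]), ltd = as<double>(plast["ltd"]);
  double win = as<double>(plast["window"]);
  double wmin = as<double>(plast["wmin"]), wmax = as<double>(plast["wmax"]);
  IntegerVector teacher = plast["teacher"]; // length N, global IO id or -1
  // per-target LTD scaling with climbing-fiber strength (teaching efficacy)
  NumericVector teach_eff = plast["efficacy"]; // length N
  int skip_trials = as<int>(plast["skip_trials"]);

  List out_id(n_trials), out_t(n_trials);
  NumericVector mean_w(n_trials);
  List snapshots;

  std::vector<int> sp_id; std::vector<double> sp_t;
  std::vector<std::vector<double> > cell_spikes(N); // per-trial, for plasticity

  // settling period: tonic dynamics only, nothing recorded
  for (int s = 0; s < warmup_steps; ++s, ++step_abs) {
    const size_t slot_now = step_abs % L;
    double *slot_ptr = &ring[slot_now * N * 2];
    for (int i = 0; i < N; ++i) {
      double gE = ge[i] * ge_d[i] + slot_ptr[2 * i];
      double gI = gi[i] * gi_d[i] + slot_ptr[2 * i + 1];
      if (gE < 1e-14) gE = 0.0;
      if (gI < 1e-14) gI = 0.0;
      slot_ptr[2 * i] = 0.0; slot_ptr[2 * i + 1] = 0.0;
      ge[i] = gE; gi[i] = gI;
      double v = V[i];
      if (Ie[i] == 0.0 && gE == 0.0 && gI == 0.0 && Ia[i] == 0.0 &&
          Id[i] == 0.0 && refr[i] <= 0.0 && v == Er[i])
        continue;
      double ia_new = Ia[i] * e2[i] + cad[i] * (v - Er[i]);
      double id_new = Id[i] * e1[i];
      if (std::fabs(ia_new) < 1e-12) ia_new = 0.0;
      if (id_new < 1e-12) id_new = 0.0;
      Ia[i] = ia_new; Id[i] = id_new;
      if (refr[i] > 0.0) {
        refr[i] -= dt;
        if (refr[i] < 1e-12) refr[i] = 0.0;
        V[i] = Vres[i];
        continue;
      }
      double Isyn = gE * (Ee[i] - v) + gI * (Ei[i] - v);
      double vinf = Er[i] + taum[i] * (Ie[i] + id_new - ia_new + Isyn) / Cm[i];
      v = vinf + (v - vinf) * em[i];
      if (std::fabs(v - Er[i]) < 1e-12) v = Er[i];
      if (v >= Vth[i]) {
        V[i] = Vres[i]; Id[i] += A1[i]; Ia[i] += A2[i]; refr[i] = Tref[i];
        const std::vector<Edge> &adj = neu_adj[i];
        for (size_t k = 0; k < adj.size(); ++k) {
          const Edge &e = adj[k];
          size_t slot = ((step_abs + e.delay) % L);
          ring[(slot * N + e.post) * 2 + e.rec] += *e.w;
        }
      } else {
        V[i] = v;
      }
    }
  }

  for (int trial = 0; trial < n_trials; ++trial) {
    sp_id.clear(); sp_t.clear();
    for (int i = 0; i < N; ++i) cell_spikes[i].clear();

    List mft = mf_trains[trial];
    IntegerVector mf_id = mft["id"]; NumericVector mf_t = mft["t"];
    List inj = inj_trains[trial];
    IntegerVector in_tg = inj["target"]; NumericVector in_t = inj["t"];
    NumericVector in_w = inj["w"]; IntegerVector in_rec = inj["rec"];
    int mf_ptr = 0, in_ptr = 0;
    const int n_mf_ev = mf_id.size(), n_in_ev = in_tg.size();

    for (int s = 0; s < n_steps; ++s, ++step_abs) {
      const double t_now = s * dt;
      // route mf spikes occurring in [t_now, t_now + dt)
      while (mf_ptr < n_mf_ev && mf_t[mf_ptr] < t_now + dt) {
        int m = mf_id[mf_ptr];
        if (m >= 0 && m < n_mf) {
          const std::vector<Edge> &adj = mf_adj[m];
          for (size_t k = 0; k < adj.size(); ++k) {
            const Edge &e = adj[k];
            size_t slot = ((step_abs + e.delay) % L);
            ring[(slot * N + e.post) * 2 + e.rec] += *e.w;
          }
        }
        ++mf_ptr;
      }
      // direct stimulus injections (US drive, lesion overlays)
      while (in_ptr < n_in_ev && in_t[in_ptr] < t_now + dt) {
        int tg = in_tg[in_ptr];
        if (in_rec[in_ptr] == 0) ge[tg] += in_w[in_ptr]; else gi[tg] += in_w[in_ptr];
        ++in_ptr;
      }

      const size_t slot_now = step_abs % L;
      double *slot_ptr = &ring[slot_now * N * 2];

      for (int i = 0; i < N; ++i) {
        // conductance decay + delayed arrivals
        double gE = ge[i] * ge_d[i] + slot_ptr[2 * i];
        double gI = gi[i] * gi_d[i] + slot_ptr[2 * i + 1];
        if (gE < 1e-14) gE = 0.0;
        if (gI < 1e-14) gI = 0.0;
        slot_ptr[2 * i] = 0.0; slot_ptr[2 * i + 1] = 0.0;
        ge[i] = gE; gi[i] = gI;

        double v = V[i];
        // idle shortcut: fully relaxed, input-free neuron
        if (Ie[i] == 0.0 && gE == 0.0 && gI == 0.0 && Ia[i] == 0.0 &&
            Id[i] == 0.0 && refr[i] <= 0.0 && v == Er[i])
          continue;

        // currents (exponential updates, V frozen over the step)
        double ia_new = Ia[i] * e2[i] + cad[i] * (v - Er[i]);
        double id_new = Id[i] * e1[i];
        if (std::fabs(ia_new) < 1e-12) ia_new = 0.0;
        if (id_new < 1e-12) id_new = 0.0;
        Ia[i] = ia_new; Id[i] = id_new;

        if (refr[i] > 0.0) {           // clamped during refractory period
          refr[i] -= dt;
          if (refr[i] < 1e-12) refr[i] = 0.0;
          V[i] = Vres[i];
          continue;
        }

        double Isyn = gE * (Ee[i] - v) + gI * (Ei[i] - v);
        double Itot = Ie[i] + id_new - ia_new + Isyn;
        double vinf = Er[i] + taum[i] * Itot / Cm[i];
        v = vinf + (v - vinf) * em[i];
        if (std::fabs(v - Er[i]) < 1e-12) v = Er[i];

        if (v >= Vth[i]) {             // spike at step end
          double tsp = (s + 1) * dt;
          sp_id.push_back(i); sp_t.push_back(tsp);
          cell_spikes[i].push_back(tsp);
          V[i] = Vres[i]; Id[i] += A1[i]; Ia[i] += A2[i]; refr[i] = Tref[i];
          const std::vector<Edge> &adj = neu_adj[i];
          for (size_t k = 0; k < adj.size(); ++k) {
            const Edge &e = adj[k];
            size_t slot = ((step_abs + e.delay) % L);
            ring[(slot * N + e.post) * 2 + e.rec] += *e.w;
          }
        } else {
          V[i] = v;
        }
      }
    }

    // --- batched pf->PC plasticity at the trial boundary
    if (plast_on && trial >= skip_trials) {
      const RawGroup &pg = rg[plast_group];
      NumericVector &w = gw[plast_group];
      for (int k = 0; k < pg.pre.size(); ++k) {
        const std::vector<double> &pf = cell_spikes[pg.pre[k]];
        if (pf.empty()) continue;
        int io = teacher[pg.post[k]];
        int n_ltd = 0;
        if (io >= 0 && !cell_spikes[io].empty()) {
          const std::vector<double> &ios = cell_spikes[io];
          for (size_t q = 0; q < pf.size(); ++q) {
            int j = first_at_or_after(ios, pf[q]);
            if (j < int(ios.size()) && ios[j] - pf[q] <= win) ++n_ltd;
          }
        }
        int n_ltp = int(pf.size()) - n_ltd;
        double nw = w[k] + ltp * n_ltp - ltd * teach_eff[pg.post[k]] * n_ltd;
        w[k] = std::min(wmax, std::max(wmin, nw));
      }
    }
    if (plast_group >= 0) {
      mean_w[trial] = mean(gw[plast_group]);
      if (snapshot_every > 0 && trial >= skip_trials &&
          ((trial + 1 - skip_trials) % snapshot_every == 0))
        snapshots.push_back(clone(gw[plast_group]));
    }

    out_id[trial] = IntegerVector(sp_id.begin(), sp_id.end());
    out_t[trial] = NumericVector(sp_t.begin(), sp_t.end());
  }

  NumericMatrix state(N, 4);
  for (int i = 0; i < N; ++i) {
    state(i, 0) = V[i]; state(i, 1) = Ia[i]; state(i, 2) = Id[i]; state(i, 3) = refr[i];
  }
  List weights(n_groups);
  for (int g = 0; g < n_groups; ++g) weights[g] = gw[g];

  return List::create(_["spike_id"] = out_id, _["spike_t"] = out_t,
                      _["weights"] = weights, _["state"] = state,
                      _["mean_w"] = mean_w, _["snapshots"] = snapshots);
}

// Single E-GLIF neuron driven by a constant current (plus optional conductance
// input train), used for rate calibration and unit checks.
// [[Rcpp::export]]
List cpp_simulate_neuron(NumericVector p, double dt, int n_steps, double I_in,
                         NumericVector spikes_in, double w_in, double tau_syn,
                         double E_rev, bool record_v,
                         double v0, double ia0, double id0) {
  const double Cm = p[CM], taum = p[TAUM], Er = p[EREST], Vth = p[VTH];
  const double Vres = p[VRESET], Tref = p[TREF], Ie = p[IE];
  const double kadp = p[KADAP], k2v = p[K2], A1v = p[A1P], A2v = p[A2P];
  const double em = std::exp(-dt / taum), e1 = std::exp(-p[K1] * dt);
  const double e2 = std::exp(-k2v * dt);
  const double cad = (k2v > 0) ? (kadp / k2v) * (1.0 - e2) : kadp * dt;
  const double gd = (tau_syn > 0) ? std::exp(-dt / tau_syn) : 0.0;

  double V = v0, Ia = ia0, Id = id0, refr = 0.0, g = 0.0;
  int sp_ptr = 0;
  std::vector<double> sp;
  NumericVector vtr(record_v ? n_steps : 0);

  for (int s = 0; s < n_steps; ++s) {
    const double t_now = s * dt;
    g *= gd;
    while (sp_ptr < spikes_in.size() && spikes_in[sp_ptr] < t_now + dt) {
      g += w_in; ++sp_ptr;
    }
    double ia_new = Ia * e2 + cad * (V - Er);
    Ia = ia_new; Id *= e1;
    if (refr > 0.0) {
      refr -= dt; V = Vres;
      if (record_v) vtr[s] = V;
      continue;
    }
    double Isyn = g * (E_rev - V);
    double vinf = Er + taum * (Ie + I_in + Id - Ia + Isyn) / Cm;
    V = vinf + (V - vinf) * em;
    if (V >= Vth) {
      sp.push_back((s + 1) * dt);
      V = Vres; Id += A1v; Ia += A2v; refr = Tref;
    }
    if (record_v) vtr[s] = V;
  }
  return List::create(_["spikes"] = NumericVector(sp.begin(), sp.end()),
                      _["V"] = vtr,
                      _["state"] = NumericVector::create(V, Ia, Id, refr));
}
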