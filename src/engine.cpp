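// Event-driven LIF network engine: Euler-Maruyama membrane integration,
// double-exponential (rise/decay) synapses with axonal delays, sinusoidal
// stimulation, and soft-bound symmetric Hebbian STDP via exponential traces.
//
// Conventions (mirrored by the R reference implementations used in tests):
//  - time unit ms; state at the start of step s is v(s*dt); the step advances
//    to v((s+1)*dt) using drift evaluated at the left endpoint.
//  - a spike detected during step s is stamped (s+1)*dt; the neuron resets to
//    its per-neuron rest value and holds it for ceil(tau_ref/dt) steps.
//  - synaptic kernels are peak-normalised double exponentials implemented as
//    the difference of two exponentially decaying accumulators per
//    (neuron, receptor class); arrivals enter both accumulators so the kernel
//    starts at 0 (causality) and reaches its unit peak g-scaled.
//  - STDP pairing is all-to-all through per-neuron pre/post traces decaying
//    with gamma_plus / gamma_minus; simultaneous (same-step) pre/post spikes
//    contribute nothing (DeltaT = 0), enforced by a two-pass update.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Deterministic normal generator (Box-Muller over mt19937_64 bits) so runs
// are bit-reproducible for a given seed regardless of libstdc++ internals.
struct NormalRNG {
  std::uint64_t s[2];
  bool have_spare = false;
  double spare = 0.0;
  explicit NormalRNG(std::uint64_t seed) {
    // splitmix64 seeding of xoshiro-style state
    std::uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      std::uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  inline std::uint64_t next_u64() {
    // xoroshiro128+
    std::uint64_t s0 = s[0], s1 = s[1];
    std::uint64_t r = s0 + s1;
    s1 ^= s0;
    s[0] = ((s0 << 55) | (s0 >> 9)) ^ s1 ^ (s1 << 14);
    s[1] = (s1 << 36) | (s1 >> 28);
    return r;
  }
  inline double unif() {  // in (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

struct Arrival { int post; int k; double w; };

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(List net, List stim, List noise, List stdp, List record,
                  double dt, double t_total, double seed) {
  // ---- unpack network -------------------------------------------------
  NumericVector tau_m   = net["tau_m"];
  NumericVector v_rest  = net["v_rest"];
  NumericVector rheo    = net["rheo"];
  double v_thr          = as<double>(net["v_thr"]);
  double tau_ref        = as<double>(net["tau_ref"]);
  bool conductance      = as<bool>(net["conductance"]);
  const int n = tau_m.size();

  IntegerVector syn_pre   = net["syn_pre"];    // 0-based
  IntegerVector syn_post  = net["syn_post"];
  NumericVector syn_g0    = net["syn_g"];
  IntegerVector syn_delay = net["syn_delay_steps"];
  IntegerVector syn_k     = net["syn_kclass"]; // 0-based receptor class
  IntegerVector syn_plast = net["syn_plastic"];
  NumericVector syn_gref  = net["syn_g0ref"];
  const int m = syn_pre.size();

  NumericVector ker_tau_r = net["ker_tau_r"];
  NumericVector ker_tau_d = net["ker_tau_d"];
  NumericVector ker_E     = net["ker_E_syn"];
  const int K = ker_tau_r.size();

  // ---- stimulation / noise / plasticity -------------------------------
  double A_s    = as<double>(stim["amplitude"]);
  double f_hz   = as<double>(stim["frequency"]);
  double theta  = as<double>(stim["phase"]);
  double t_on   = as<double>(stim["t_on"]);
  double t_off  = as<double>(stim["t_off"]);
  double mu     = as<double>(noise["mu"]);
  double sigma  = as<double>(noise["sigma"]);

  bool   stdp_on = as<bool>(stdp["enabled"]);
  double A_plus  = as<double>(stdp["A_plus"]);
  double A_minus = as<double>(stdp["A_minus"]);
  double g_plus  = as<double>(stdp["gamma_plus"]);
  double g_minus = as<double>(stdp["gamma_minus"]);
  double gmax_f  = as<double>(stdp["g_max_factor"]);
  double gmin_f  = as<double>(stdp["g_min_factor"]);

  // ---- recording plan --------------------------------------------------
  bool record_spikes       = as<bool>(record["spikes"]);
  bool passive             = as<bool>(record["passive"]);
  IntegerVector snap_steps = record["snapshot_steps"];   // sorted; -1 => initial
  IntegerVector snap_idx   = record["snapshot_idx"];     // 0-based synapse ids
  IntegerVector v_idx      = record["v_idx"];            // 0-based neuron ids
  int v_stride             = as<int>(record["v_stride"]);
  IntegerVector drive_grp  = record["drive_group"];      // per neuron, -1 none
  int drive_stride         = as<int>(record["drive_stride"]);
  NumericVector v0         = record["v0"];

  const int nsteps = (int) std::lround(t_total / dt);
  const int ref_steps = (int) std::lround(tau_ref / dt);
  const double sqrtdt = std::sqrt(dt);
  const double two_pi = 6.283185307179586476925286766559;

  // ---- derived per-class constants -------------------------------------
  std::vector<double> dec_r(K), dec_d(K), knorm(K);
  for (int k = 0; k < K; ++k) {
    double tr = ker_tau_r[k], td = ker_tau_d[k];
    if (!(tr > 0.0 && td > tr)) stop("synaptic kernel requires 0 < tau_r < tau_d");
    dec_r[k] = std::exp(-dt / tr);
    dec_d[k] = std::exp(-dt / td);
    double speak = tr * td / (td - tr) * std::log(td / tr);
    knorm[k] = std::exp(-speak / td) - std::exp(-speak / tr);
  }

  // ---- CSR adjacency ----------------------------------------------------
  std::vector<int> out_off(n + 1, 0), out_syn(m);
  std::vector<int> inp_off(n + 1, 0), inp_syn;
  {
    for (int s = 0; s < m; ++s) out_off[syn_pre[s] + 1]++;
    for (int i = 0; i < n; ++i) out_off[i + 1] += out_off[i];
    std::vector<int> cur(out_off.begin(), out_off.end() - 1);
    for (int s = 0; s < m; ++s) out_syn[cur[syn_pre[s]]++] = s;
    int mp = 0;
    for (int s = 0; s < m; ++s) if (syn_plast[s]) ++mp;
    inp_syn.resize(mp);
    for (int s = 0; s < m; ++s) if (syn_plast[s]) inp_off[syn_post[s] + 1]++;
    for (int i = 0; i < n; ++i) inp_off[i + 1] += inp_off[i];
    std::vector<int> cur2(inp_off.begin(), inp_off.end() - 1);
    for (int s = 0; s < m; ++s) if (syn_plast[s]) inp_syn[cur2[syn_post[s]]++] = s;
  }

  // ---- state ------------------------------------------------------------
  // Weights are evolved in baseline-normalised units gh = g / g0_ref, so the
  // dimensionless STDP rates apply identically across weight scales (pair
  // motif in mV, network in a.u.); physical weights are restored on output
  // and for synaptic deliveries.
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<int> refc(n, 0);
  std::vector<double> g(m);
  for (int s = 0; s < m; ++s) g[s] = syn_g0[s] / syn_gref[s];
  // synaptic accumulators, [k][i]
  std::vector<std::vector<double> > xr(K, std::vector<double>(n, 0.0));
  std::vector<std::vector<double> > xd(K, std::vector<double>(n, 0.0));
  // STDP traces
  std::vector<double> trp(n, 0.0), trm(n, 0.0), tlast(n, 0.0);

  int max_delay = 1;
  for (int s = 0; s < m; ++s) {
    if (syn_delay[s] < 1) stop("axonal delay must be at least one time step");
    if (syn_delay[s] > max_delay) max_delay = syn_delay[s];
  }
  // +2: a spike stamped (s+1)*dt with delay d steps is delivered at the start
  // of step s+1+d, so the kernel clock is exactly t - t_sp - delay thereafter
  const int ring_n = max_delay + 2;
  std::vector<std::vector<Arrival> > ring(ring_n);

  NormalRNG rng((std::uint64_t) seed);

  // ---- output buffers ----------------------------------------------------
  std::vector<int> sp_id; std::vector<double> sp_t;
  if (record_spikes) { sp_id.reserve(1 << 16); sp_t.reserve(1 << 16); }

  const int n_snap = snap_steps.size();
  NumericMatrix snapshots(snap_idx.size(), n_snap);
  int snap_ptr = 0;
  while (snap_ptr < n_snap && snap_steps[snap_ptr] < 0) {
    for (int r = 0; r < snap_idx.size(); ++r)
      snapshots(r, snap_ptr) = g[snap_idx[r]] * syn_gref[snap_idx[r]];
    ++snap_ptr;
  }

  const int n_vrec = v_idx.size() > 0 ? (nsteps / v_stride + 1) : 0;
  NumericMatrix v_trace(n_vrec, v_idx.size());
  NumericVector v_times(n_vrec);
  int v_row = 0;

  int n_grp = 0;
  for (int i = 0; i < n; ++i) if (drive_grp[i] + 1 > n_grp) n_grp = drive_grp[i] + 1;
  std::vector<int> grp_count(n_grp > 0 ? n_grp : 1, 0);
  for (int i = 0; i < n; ++i) if (drive_grp[i] >= 0) grp_count[drive_grp[i]]++;
  const int n_drec = (n_grp > 0) ? (nsteps / drive_stride + 1) : 0;
  NumericMatrix drive_trace(n_drec, n_grp);
  NumericVector drive_times(n_drec);
  int d_row = 0;
  std::vector<double> grp_acc(n_grp > 0 ? n_grp : 1, 0.0);

  std::vector<int> spikers; spikers.reserve(256);

  // ---- main loop ----------------------------------------------------------
  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;

    // decay accumulators from t-dt to t, then deliver arrivals whose kernel
    // clock is zero at t (so the first nonzero drive appears one step later)
    for (int k = 0; k < K; ++k) {
      double fr = dec_r[k], fd = dec_d[k];
      std::vector<double>& xrk = xr[k];
      std::vector<double>& xdk = xd[k];
      for (int i = 0; i < n; ++i) { xrk[i] *= fr; xdk[i] *= fd; }
    }
    std::vector<Arrival>& slot = ring[step % ring_n];
    for (size_t a = 0; a < slot.size(); ++a) {
      xr[slot[a].k][slot[a].post] += slot[a].w;
      xd[slot[a].k][slot[a].post] += slot[a].w;
    }
    slot.clear();

    const bool stim_live = (t >= t_on && t < t_off && A_s != 0.0);
    const double I_s = stim_live ? A_s * std::sin(two_pi * f_hz * t / 1000.0 + theta) : 0.0;

    const bool rec_v = (v_idx.size() > 0 && step % v_stride == 0);
    const bool rec_d = (n_grp > 0 && step % drive_stride == 0);
    if (rec_d) std::fill(grp_acc.begin(), grp_acc.end(), 0.0);
    if (rec_v) {
      for (int r = 0; r < v_idx.size(); ++r) v_trace(v_row, r) = v[v_idx[r]];
      v_times[v_row] = t;
      ++v_row;
    }

    spikers.clear();
    for (int i = 0; i < n; ++i) {
      // read the synaptic drive at time t
      double drive = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = xd[k][i] - xr[k][i];
        drive += conductance ? a * (ker_E[k] - v[i]) : a;
      }
      if (rec_d && drive_grp[i] >= 0) grp_acc[drive_grp[i]] += drive;

      if (refc[i] > 0) { --refc[i]; continue; }  // clamped, inputs ignored

      double dv = (dt / tau_m[i]) * (v_rest[i] - v[i] + mu + rheo[i] + drive + I_s);
      if (sigma > 0.0) dv += (sigma / tau_m[i]) * sqrtdt * rng.norm();
      v[i] += dv;
      if (!std::isfinite(v[i])) stop("membrane potential became non-finite at t = %f ms", t);
      if (!passive && v[i] >= v_thr) spikers.push_back(i);
    }

    if (rec_d) {
      for (int gix = 0; gix < n_grp; ++gix)
        drive_trace(d_row, gix) = grp_count[gix] > 0 ? grp_acc[gix] / grp_count[gix] : NA_REAL;
      drive_times[d_row] = t;
      ++d_row;
    }

    if (!spikers.empty()) {
      const double t_sp = (step + 1) * dt;
      // pass 1: STDP updates against traces excluding this step's spikes
      if (stdp_on) {
        for (size_t q = 0; q < spikers.size(); ++q) {
          const int nn = spikers[q];
          // decay helper (lazy, per neuron touched)
          for (int p = inp_off[nn]; p < inp_off[nn + 1]; ++p) {
            const int s = inp_syn[p];
            const int i_pre = syn_pre[s];
            if (tlast[i_pre] < t_sp) {
              trp[i_pre] *= std::exp(-(t_sp - tlast[i_pre]) / g_plus);
              trm[i_pre] *= std::exp(-(t_sp - tlast[i_pre]) / g_minus);
              tlast[i_pre] = t_sp;
            }
            g[s] += A_plus * (1.0 - g[s] / gmax_f) * trp[i_pre];
            if (g[s] > gmax_f) g[s] = gmax_f;
            if (g[s] < gmin_f) g[s] = gmin_f;
          }
          for (int p = out_off[nn]; p < out_off[nn + 1]; ++p) {
            const int s = out_syn[p];
            if (!syn_plast[s]) continue;
            const int j_post = syn_post[s];
            if (tlast[j_post] < t_sp) {
              trp[j_post] *= std::exp(-(t_sp - tlast[j_post]) / g_plus);
              trm[j_post] *= std::exp(-(t_sp - tlast[j_post]) / g_minus);
              tlast[j_post] = t_sp;
            }
            g[s] -= A_minus * g[s] * trm[j_post];  // g here is g/g0_ref
            if (g[s] < gmin_f) g[s] = gmin_f;
            if (g[s] > gmax_f) g[s] = gmax_f;
          }
        }
      }
      // pass 2: reset, trace increments, delayed deliveries, spike record
      for (size_t q = 0; q < spikers.size(); ++q) {
        const int nn = spikers[q];
        v[nn] = v_rest[nn];
        refc[nn] = ref_steps;
        if (stdp_on) {
          if (tlast[nn] < t_sp) {
            trp[nn] *= std::exp(-(t_sp - tlast[nn]) / g_plus);
            trm[nn] *= std::exp(-(t_sp - tlast[nn]) / g_minus);
            tlast[nn] = t_sp;
          }
          trp[nn] += 1.0;
          trm[nn] += 1.0;
        }
        for (int p = out_off[nn]; p < out_off[nn + 1]; ++p) {
          const int s = out_syn[p];
          Arrival ar;
          ar.post = syn_post[s];
          ar.k = syn_k[s];
          ar.w = g[s] * syn_gref[s] / knorm[ar.k];
          ring[(step + 1 + syn_delay[s]) % ring_n].push_back(ar);
        }
        if (record_spikes) { sp_id.push_back(nn + 1); sp_t.push_back(t_sp); }
      }
    }

    // weight snapshots stamped after completing this step
    while (snap_ptr < n_snap && snap_steps[snap_ptr] == step) {
      for (int r = 0; r < snap_idx.size(); ++r)
        snapshots(r, snap_ptr) = g[snap_idx[r]] * syn_gref[snap_idx[r]];
      ++snap_ptr;
    }
  }
  for (int s = 0; s < m; ++s) g[s] *= syn_gref[s];  // back to physical units

  // final v recording row (state at t_total) if stride lands there
  return List::create(
    _["spike_neuron"] = wrap(sp_id),
    _["spike_time"]   = wrap(sp_t),
    _["g_final"]      = wrap(g),
    _["snapshots"]    = snapshots,
    _["v"]            = v_trace,
    _["v_times"]      = v_times,
    _["drive"]        = drive_trace,
    _["drive_times"]  = drive_times,
    _["v_final"]      = wrap(v));
}
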