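// Simulation core: Euler-Maruyama integration of the two-cell ELL network
// (superficial pyramidal cells with DAP-mediated bursting + two disjoint
// banks of granule cells), streaming generation of the structured low-pass
// filtered noise, online burst classification and burst-timing-dependent
// plasticity.  All times in ms, voltages in mV, currents in uA/cm2,
// conductances in mS/cm2 internally.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// causal order-n IIR filter, direct form II transposed; coefficients from
// signal::butter() on the R side (a[0] assumed 1).
struct IIR {
  std::vector<double> b, a, z;
  void init(const NumericVector& bb, const NumericVector& aa) {
    b.assign(bb.begin(), bb.end());
    a.assign(aa.begin(), aa.end());
    z.assign(b.size() - 1, 0.0);
  }
  inline double step(double x) {
    const double y = b[0] * x + z[0];
    const size_t n = z.size();
    for (size_t i = 0; i < n; ++i) {
      const double znext = (i + 1 < n) ? z[i + 1] : 0.0;
      z[i] = b[i + 1] * x + znext - a[i + 1] * y;
    }
    return y;
  }
};

// one named substream: its own RNG + its own filter state, so any single
// process is reproducible in isolation regardless of which other streams
// are being consumed.
struct Stream {
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss{0.0, 1.0};
  IIR filt;
  double scale = 1.0;  // 1/sd of the filtered process
  void seed_stream(uint32_t master, uint32_t trial, uint32_t id,
                   const NumericVector& b, const NumericVector& a,
                   double sc) {
    std::seed_seq ss{master, trial, id};
    rng.seed(ss);
    gauss.reset();
    filt.init(b, a);
    scale = sc;
  }
  inline double draw() { return filt.step(gauss(rng)) * scale; }
};

inline double halfrect(double x) { return x > 0.0 ? x : 0.0; }

// alpha kernel s(t, a) = (t/a^2) exp(-t/a) for t > 0 (area-normalised,
// peak 1/(a*e) at t = a)
inline double alpha_kernel(double t, double a) {
  if (t <= 0.0) return 0.0;
  return (t / (a * a)) * std::exp(-t / a);
}

struct BurstState {
  std::vector<double> st;   // spike times
  std::vector<int> inb;     // 0 = unassigned, 2/4 = burst size
  std::vector<double> burst_onset;
  std::vector<int> burst_size;
};

// online classification rule applied at each new spike: try the new spike
// with its three predecessors as a 4-spike burst (none already assigned,
// first-to-last span <= 45 ms); failing that, test the 4th- and 5th-most
// recent spikes as a 2-spike burst (neither assigned, <= 15 ms apart).
// Returns burst size classified at this spike (0 if none); onset via out.
inline int classify_step(BurstState& bs, double& onset_out) {
  const int n = static_cast<int>(bs.st.size()) - 1;  // index of new spike
  if (n >= 3 && bs.inb[n - 1] == 0 && bs.inb[n - 2] == 0 &&
      bs.inb[n - 3] == 0 && (bs.st[n] - bs.st[n - 3]) <= 45.0) {
    for (int k = n - 3; k <= n; ++k) bs.inb[k] = 4;
    onset_out = bs.st[n - 3];
    bs.burst_onset.push_back(onset_out);
    bs.burst_size.push_back(4);
    return 4;
  }
  if (n >= 4) {
    const int i4 = n - 3, i5 = n - 4;
    if (bs.inb[i4] == 0 && bs.inb[i5] == 0 &&
        (bs.st[i4] - bs.st[i5]) <= 15.0) {
      bs.inb[i4] = 2;
      bs.inb[i5] = 2;
      onset_out = bs.st[i5];
      bs.burst_onset.push_back(onset_out);
      bs.burst_size.push_back(2);
      return 2;
    }
  }
  return 0;
}

// x modulo P into [0, P)
inline double mod_pos(double x, double P) {
  return x - P * std::floor(x / P);
}

// circular difference into (-P/2, P/2]
inline double circ_diff(double x, double P) {
  double d = mod_pos(x, P);
  if (d > P / 2.0) d -= P;
  return d;
}

}  // namespace

// [[Rcpp::export]]
List sim_network_cpp(List par) {
  // --- unpack ----------------------------------------------------------
  const double dt = as<double>(par["dt"]);                 // ms
  const double duration = as<double>(par["duration_ms"]);  // ms
  const double burn = as<double>(par["burn_ms"]);
  const double f = as<double>(par["f"]);                   // Hz
  const double kappa = as<double>(par["kappa"]);
  const bool feedback = as<bool>(par["feedback"]);
  const double c = as<double>(par["c"]);
  const double e = as<double>(par["e"]);
  const double sigma = as<double>(par["sigma"]);
  const double rho = as<double>(par["rho"]);
  const int n_gc = as<int>(par["n_gc"]);

  const double Cm = as<double>(par["C"]);
  const double gl = as<double>(par["g_leak"]);
  const double El = as<double>(par["E_leak"]);
  const double Ibias = as<double>(par["I"]);
  const double Vth = as<double>(par["V_threshold"]);
  const double Vrest = as<double>(par["V_rest"]);
  const double rs = as<double>(par["r_s"]);
  const double gGABA = as<double>(par["g_GABA"]);
  const double EGABA = as<double>(par["E_GABA"]);
  const double EAMPA = as<double>(par["E_AMPA"]);
  const double gmax = as<double>(par["g_max"]);
  const double tauA = as<double>(par["tau_AMPA"]);
  const double I_gc = as<double>(par["I_gc"]);
  const double kappa_gc = as<double>(par["kappa_gc"]);

  const double dapA = as<double>(par["A"]);
  const double dapB = as<double>(par["B"]);
  const double dapD = as<double>(par["D"]);
  const double dapE = as<double>(par["E"]);
  const double dapGamma = as<double>(par["gamma"]);
  const double dapAlpha = as<double>(par["alpha"]);
  const double dapTau = as<double>(par["tau"]);

  const bool plastic = as<bool>(par["plasticity"]);
  const double eta2 = as<double>(par["eta_2"]);
  const double eta4 = as<double>(par["eta_4"]);
  const double Lw2 = as<double>(par["L_W2"]);
  const double Lw4 = as<double>(par["L_W4"]);
  const double tauW = as<double>(par["tau_w"]);  // s

  NumericMatrix w0 = as<NumericMatrix>(par["weights"]);  // 2 x n_gc
  const bool record_gc = as<bool>(par["record_gc"]);
  const bool record_v = as<bool>(par["record_v"]);
  NumericVector snap_times = as<NumericVector>(par["snapshot_times"]);  // ms

  const uint32_t master = static_cast<uint32_t>(as<double>(par["seed"]));
  const uint32_t trial = static_cast<uint32_t>(as<double>(par["trial"]));
  NumericVector fb = as<NumericVector>(par["filt_b"]);
  NumericVector fa = as<NumericVector>(par["filt_a"]);
  const double fscale = as<double>(par["filt_scale"]);

  // --- setup -----------------------------------------------------------
  const double P = 1000.0 / f;  // stimulus period, ms
  const double two_pi_f = 2.0 * M_PI * f / 1000.0;
  const long n_steps = static_cast<long>(std::llround((duration + burn) / dt));
  const long burn_steps = static_cast<long>(std::llround(burn / dt));
  const int ref_steps = static_cast<int>(std::ceil(rs / dt));
  const double decayA = std::exp(-dt / tauA);
  const double dt_s = dt / 1000.0;

  const double sqc = std::sqrt(c), sqcm = std::sqrt(1.0 - c);
  const double sqe = std::sqrt(e), sqem = std::sqrt(1.0 - e);
  const bool need_private = feedback && (e < 1.0) && rho > 0.0;

  Stream sh, u1, u2;
  sh.seed_stream(master, trial, 0u, fb, fa, fscale);
  u1.seed_stream(master, trial, 1u, fb, fa, fscale);
  u2.seed_stream(master, trial, 2u, fb, fa, fscale);
  std::vector<Stream> priv;
  if (need_private) {
    priv.resize(2 * n_gc);
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < n_gc; ++i)
        priv[j * n_gc + i].seed_stream(master, trial,
                                       3u + static_cast<uint32_t>(j * n_gc + i),
                                       fb, fa, fscale);
  }

  // granule delays d_i tile one stimulus period; same tiling in each bank
  std::vector<double> sinph(n_gc), cosph(n_gc), tpre_phase(n_gc);
  for (int i = 0; i < n_gc; ++i) {
    const double d = P * static_cast<double>(i) / n_gc;
    sinph[i] = std::sin(two_pi_f * d);
    cosph[i] = std::cos(two_pi_f * d);
    tpre_phase[i] = mod_pos(d + P / 4.0, P);  // delayed-sinusoid maximum
  }

  // state
  double Vsp[2] = {Vrest, Vrest};
  int ref_sp[2] = {0, 0};
  double t_n[2] = {-1e18, -1e18}, t_nm1[2] = {-1e18, -1e18};
  double q_dap[2] = {1.0, 1.0};
  double r_d[2] = {dapD, dapD};
  int nsp_spikes[2] = {0, 0};
  double Gsyn[2] = {0.0, 0.0};

  std::vector<double> Vgc;
  std::vector<int> ref_gc;
  if (feedback) {
    Vgc.assign(2 * n_gc, Vrest);
    ref_gc.assign(2 * n_gc, 0);
  }
  NumericMatrix w(clone(w0));

  std::vector<double> sp_out[2];
  std::vector<std::vector<double>> gc_out;
  if (record_gc && feedback) gc_out.assign(2 * n_gc, {});
  BurstState bs[2];

  const int n_snap = snap_times.size();
  NumericMatrix snaps(n_snap > 0 ? n_snap : 1, 2 * n_gc);
  int snap_idx = 0;

  std::vector<double> vtrace[2];
  if (record_v) {
    vtrace[0].reserve(n_steps - burn_steps);
    vtrace[1].reserve(n_steps - burn_steps);
  }

  // potentiation per step: w <- 1 - (1 - w) * exp(-dt_s / tauW), exact
  const double pot_fac = std::exp(-dt_s / tauW);

  // --- main loop -------------------------------------------------------
  for (long k = 0; k < n_steps; ++k) {
    const double t = (k - burn_steps) * dt;        // state time
    const double tn = t + dt;                      // time after this step
    const double th = two_pi_f * tn;
    const double sth = std::sin(th), cth = std::cos(th);

    // noise: compose filtered unit-variance base streams
    const double xsh = sh.draw(), xu1 = u1.draw(), xu2 = u2.draw();
    const double xi_sp[2] = {sqc * xsh + sqcm * xu1, sqc * xsh + sqcm * xu2};

    // granule cells
    if (feedback) {
      for (int j = 0; j < 2; ++j) {
        const double inherited = sqe * xi_sp[j];
        for (int i = 0; i < n_gc; ++i) {
          const int idx = j * n_gc + i;
          if (ref_gc[idx] > 0) {
            --ref_gc[idx];
            Vgc[idx] = Vrest;
            continue;
          }
          double xi = inherited;
          if (need_private) xi += sqem * priv[idx].draw();
          // delayed sinusoidal drive relayed by the deep pyramidal cells
          const double drive =
              kappa_gc * (sth * cosph[i] - cth * sinph[i]);
          const double dV =
              dt * (-gl * (Vgc[idx] - El) + I_gc + rho * xi + drive) / Cm;
          double V = Vgc[idx] + dV;
          if (V >= Vth) {
            V = Vrest;
            ref_gc[idx] = ref_steps;
            if (tn >= 0.0 && tn < duration) {
              Gsyn[j] += gmax * w(j, i);
              if (record_gc) gc_out[idx].push_back(tn);
            } else {
              Gsyn[j] += gmax * w(j, i);  // burn-in spikes still drive synapse
            }
          }
          Vgc[idx] = V;
        }
      }
    }

    // synaptic conductance decay (single-exponential pool per SP cell,
    // exact because all synapses share tau_AMPA; per-spike increments are
    // scaled by the weight at spike time)
    Gsyn[0] *= decayA;
    Gsyn[1] *= decayA;

    // SP cells
    const double stim = halfrect(kappa * sth);
    for (int i = 0; i < 2; ++i) {
      if (ref_sp[i] > 0) {
        --ref_sp[i];
        Vsp[i] = Vrest;
        if (record_v && tn >= 0.0 && tn < duration) vtrace[i].push_back(Vrest);
        // dendritic refractory state keeps evolving during the somatic clamp
        r_d[i] += dt * (dapD - r_d[i]) / dapE;
        continue;
      }
      // DAP from the most recent somatic spike; gamma is the
      // dendro-somatic coupling scale
      const double ts = tn - t_n[i] - rs;
      const double dap =
          dapGamma * dapAlpha * q_dap[i] * alpha_kernel(ts, dapTau);
      double syn = 0.0;
      if (feedback)
        syn = -gGABA * (Vsp[i] - EGABA) - Gsyn[i] * (Vsp[i] - EAMPA);
      const double dV = dt * (-gl * (Vsp[i] - El) + Ibias + sigma * xi_sp[i] +
                              stim + dap + syn) /
                        Cm;
      double V = Vsp[i] + dV;
      if (V >= Vth) {
        // somatic spike: reset, clamp, update DAP/dendritic machinery
        V = Vrest;
        ref_sp[i] = ref_steps;
        const double isi = tn - t_n[i];
        const bool success = (nsp_spikes[i] == 0) || (isi > r_d[i]);
        q_dap[i] = success ? 1.0 : dapA * q_dap[i];
        r_d[i] = dapB * r_d[i];
        t_nm1[i] = t_n[i];
        t_n[i] = tn;
        ++nsp_spikes[i];
        if (tn >= 0.0 && tn < duration) sp_out[i].push_back(tn);
        if (plastic && tn >= 0.0) {
          bs[i].st.push_back(tn);
          bs[i].inb.push_back(0);
          double onset;
          const int g = classify_step(bs[i], onset);
          if (g > 0) {
            const double eta = (g == 4) ? eta4 : eta2;
            const double half = ((g == 4) ? Lw4 : Lw2) / 2.0;
            const double tpost = mod_pos(onset, P);
            // multiplicative depression keeps the equilibrium profile
            // graded: w_eq = 1 / (1 + eta * r_burst * tau_w)
            for (int s = 0; s < n_gc; ++s) {
              if (std::fabs(circ_diff(tpre_phase[s] - tpost, P)) <= half) {
                w(i, s) *= (1.0 - eta);
              }
            }
          }
        }
      }
      Vsp[i] = V;
      r_d[i] += dt * (dapD - r_d[i]) / dapE;
      if (record_v && tn >= 0.0 && tn < duration) vtrace[i].push_back(V);
    }

    // slow non-associative potentiation toward w = 1 (plasticity acts
    // only during the recorded epoch, not the burn-in)
    if (plastic && tn >= 0.0) {
      for (int j = 0; j < 2; ++j)
        for (int s = 0; s < n_gc; ++s)
          w(j, s) = 1.0 - (1.0 - w(j, s)) * pot_fac;
    }

    if (n_snap > 0 && snap_idx < n_snap && tn >= snap_times[snap_idx]) {
      for (int j = 0; j < 2; ++j)
        for (int s = 0; s < n_gc; ++s) snaps(snap_idx, j * n_gc + s) = w(j, s);
      ++snap_idx;
    }

    if ((k & 0x3FFF) == 0) {
      if (!std::isfinite(Vsp[0]) || !std::isfinite(Vsp[1]))
        stop("non-finite SP voltage at t = %f ms", t);
    }
  }

  // --- pack results ----------------------------------------------------
  List out;
  out["sp1"] = NumericVector(sp_out[0].begin(), sp_out[0].end());
  out["sp2"] = NumericVector(sp_out[1].begin(), sp_out[1].end());
  out["weights"] = w;
  if (n_snap > 0) out["snapshots"] = snaps;
  if (record_gc && feedback) {
    List g(2 * n_gc);
    for (int i = 0; i < 2 * n_gc; ++i)
      g[i] = NumericVector(gc_out[i].begin(), gc_out[i].end());
    out["gc"] = g;
  }
  if (record_v) {
    out["v1"] = NumericVector(vtrace[0].begin(), vtrace[0].end());
    out["v2"] = NumericVector(vtrace[1].begin(), vtrace[1].end());
  }
  if (plastic) {
    out["burst_onset1"] = NumericVector(bs[0].burst_onset.begin(), bs[0].burst_onset.end());
    out["burst_size1"] = IntegerVector(bs[0].burst_size.begin(), bs[0].burst_size.end());
    out["burst_onset2"] = NumericVector(bs[1].burst_onset.begin(), bs[1].burst_onset.end());
    out["burst_size2"] = IntegerVector(bs[1].burst_size.begin(), bs[1].burst_size.end());
  }
  return out;
}

// [[Rcpp::export]]
List classify_bursts_cpp(NumericVector spike_times) {
  const int n = spike_times.size();
  for (int i = 1; i < n; ++i)
    if (spike_times[i] <= spike_times[i - 1])
      stop("spike times must be strictly increasing");
  BurstState bs;
  std::vector<int> burst_id(n, 0);
  std::vector<int> member_of;  // burst index per assigned spike
  for (int i = 0; i < n; ++i) {
    bs.st.push_back(spike_times[i]);
    bs.inb.push_back(0);
    double onset;
    const int g = classify_step(bs, onset);
    if (g == 4) {
      const int bidx = static_cast<int>(bs.burst_onset.size());
      for (int k = i - 3; k <= i; ++k) burst_id[k] = bidx;
    } else if (g == 2) {
      const int bidx = static_cast<int>(bs.burst_onset.size());
      burst_id[i - 3] = bidx;
      burst_id[i - 4] = bidx;
    }
  }
  return List::create(
      _["burst_id"] = IntegerVector(burst_id.begin(), burst_id.end()),
      _["onset"] = NumericVector(bs.burst_onset.begin(), bs.burst_onset.end()),
      _["size"] = IntegerVector(bs.burst_size.begin(), bs.burst_size.end()));
}

// [[Rcpp::export]]
List noise_bundle_cpp(int n, double c, double e, int n_gc_out, int n_gc,
                      double seed, double trial, NumericVector filt_b,
                      NumericVector filt_a, double filt_scale, int warmup) {
  const uint32_t master = static_cast<uint32_t>(seed);
  const uint32_t tr = static_cast<uint32_t>(trial);
  Stream sh, u1, u2;
  sh.seed_stream(master, tr, 0u, filt_b, filt_a, filt_scale);
  u1.seed_stream(master, tr, 1u, filt_b, filt_a, filt_scale);
  u2.seed_stream(master, tr, 2u, filt_b, filt_a, filt_scale);
  std::vector<Stream> priv(2 * n_gc_out);
  for (int j = 0; j < 2; ++j)
    for (int i = 0; i < n_gc_out; ++i)
      priv[j * n_gc_out + i].seed_stream(
          master, tr, 3u + static_cast<uint32_t>(j * n_gc + i), filt_b, filt_a,
          filt_scale);

  const double sqc = std::sqrt(c), sqcm = std::sqrt(1.0 - c);
  const double sqe = std::sqrt(e), sqem = std::sqrt(1.0 - e);

  NumericMatrix sp(n, 2);
  NumericMatrix gc1(n, n_gc_out), gc2(n, n_gc_out);
  for (int k = -warmup; k < n; ++k) {
    const double xsh = sh.draw(), xu1 = u1.draw(), xu2 = u2.draw();
    const double s1 = sqc * xsh + sqcm * xu1;
    const double s2 = sqc * xsh + sqcm * xu2;
    std::vector<double> pv(2 * n_gc_out);
    for (int i = 0; i < 2 * n_gc_out; ++i) pv[i] = priv[i].draw();
    if (k < 0) continue;
    sp(k, 0) = s1;
    sp(k, 1) = s2;
    for (int i = 0; i < n_gc_out; ++i) {
      gc1(k, i) = sqe * s1 + sqem * pv[i];
      gc2(k, i) = sqe * s2 + sqem * pv[n_gc_out + i];
    }
  }
  return List::create(_["sp"] = sp, _["gc1"] = gc1, _["gc2"] = gc2);
}
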