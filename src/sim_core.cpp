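// Fixed-step RK4 integrator for a conductance-based network of
// Hodgkin-Huxley neurons with a slow potassium (M-type) adaptation current
// and exponentially decaying conductance-jump synapses.
//
// Performance notes: voltage-dependent rate functions are tabulated once per
// call (linear interpolation, 0.05 mV grid) and the per-neuron synaptic input
// sums are maintained incrementally -- they decay by the same factor as every
// outgoing conductance, so only spikes touch the adjacency structure.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

// The inner loop dominates total run time; request the full high-optimization
// pass set for this translation unit, with a runtime-dispatched AVX2 clone of
// the integrator where the toolchain supports it.
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3","unroll-loops","tree-vectorize","split-paths", \
  "gcse-after-reload","ipa-cp-clone","peel-loops","predictive-commoning", \
  "tree-partial-pre","split-loops","unswitch-loops")
#define SIM_CLONES __attribute__((target_clones("default", "avx2")))
#else
#define SIM_CLONES
#endif

static inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1) with the removable singularity at x = 0
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 - 0.5 * r);
  return x / (std::expm1(r));
}

// Interleaved rate tables, 8 doubles per voltage grid point, stored in the
// form that makes each gate derivative a single fused multiply-add:
// dm/dt = a - (a+b) m, dp/dt = pinf/taup - p/taup.
// order: am, am+bm, ah, ah+bh, an, an+bn, pinf/taup, 1/taup
struct RateTabs {
  double vmin, inv_dv, xmax;
  int npt;
  std::vector<double> tab;
};

static RateTabs build_tabs(double v_t, double tau_max) {
  RateTabs T;
  const double vmin = -150.0, vmax = 100.0, dv = 0.05;
  T.vmin = vmin;
  T.inv_dv = 1.0 / dv;
  T.npt = (int)std::floor((vmax - vmin) / dv) + 2;
  T.xmax = (double)(T.npt - 2) + 0.999999;
  T.tab.resize(8 * T.npt);
  for (int i = 0; i < T.npt; ++i) {
    double V = vmin + i * dv;
    double u = V - v_t;
    double* r = &T.tab[8 * i];
    double am = 0.32 * vtrap(13.0 - u, 4.0);
    double bm = 0.28 * vtrap(u - 40.0, 5.0);
    double ah = 0.128 * std::exp((17.0 - u) / 18.0);
    double bh = 4.0 / (1.0 + std::exp((40.0 - u) / 5.0));
    double an = 0.032 * vtrap(15.0 - u, 5.0);
    double bn = 0.5 * std::exp((10.0 - u) / 40.0);
    double pinf = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
    double ptin = (3.3 * std::exp((V + 35.0) / 20.0) +
                   std::exp(-(V + 35.0) / 20.0)) / tau_max;
    r[0] = am; r[1] = am + bm;
    r[2] = ah; r[3] = ah + bh;
    r[4] = an; r[5] = an + bn;
    r[6] = pinf * ptin; r[7] = ptin;
  }
  return T;
}

struct Pars {
  double C, gL, EL, gNa, ENa, gK, EK, gM;
  double Ee, Ei;       // synaptic reversal potentials
  double thr;          // spike detection threshold (mV)
  double lockout;      // refractory for detection (ms)
  double guard;        // |V| blow-up guard (mV)
};

// Derivatives of the 5-dim single-neuron state; synaptic input and external
// drive enter as instantaneous conductances/currents.
static inline void deriv(const RateTabs& T, const Pars& P,
                         double V, double m, double h, double n, double p,
                         double Ge, double Gi, double Iin,
                         double& dV, double& dm, double& dh,
                         double& dn, double& dp) {
  double x = (V - T.vmin) * T.inv_dv;
  if (x < 0.0) x = 0.0;
  if (x > T.xmax) x = T.xmax;
  int i = (int)x;
  double w = x - i;
  const double* __restrict r0 = &T.tab[8 * i];
  const double* __restrict r1 = r0 + 8;
  double am = r0[0] + w * (r1[0] - r0[0]);
  double sm = r0[1] + w * (r1[1] - r0[1]);
  double ah = r0[2] + w * (r1[2] - r0[2]);
  double sh = r0[3] + w * (r1[3] - r0[3]);
  double an = r0[4] + w * (r1[4] - r0[4]);
  double sn = r0[5] + w * (r1[5] - r0[5]);
  double pq = r0[6] + w * (r1[6] - r0[6]);
  double pt = r0[7] + w * (r1[7] - r0[7]);
  double m3 = m * m * m;
  double n2 = n * n;
  double gNam = P.gNa * m3 * h;
  double gKn = P.gK * n2 * n2 + P.gM * p;
  // total-conductance form of the driving-force currents:
  // dV = (sum_k g_k E_k - (sum_k g_k) V + I) / C
  double gsum = P.gL + gNam + gKn + Ge + Gi;
  double esum = P.gL * P.EL + gNam * P.ENa + gKn * P.EK +
    Ge * P.Ee + Gi * P.Ei;
  dV = (esum - gsum * V + Iin) / P.C;
  dm = am - sm * m;
  dh = ah - sh * h;
  dn = an - sn * n;
  dp = pq - pt * p;
}

// [[Rcpp::export]]
SIM_CLONES
List sim_core(int n_neurons,
              IntegerVector tgt_ptr,    // CSR row pointer by presynaptic id, length n+1
              IntegerVector tgt_idx,    // 0-based postsynaptic targets
              LogicalVector is_exc,
              List par,                 // scalar model parameters (internal units)
              double duration, double dt, int seed,
              List control,             // closed-loop controller spec
              List record) {            // trace recording spec
  Pars P;
  P.C   = as<double>(par["C"]);
  P.gL  = as<double>(par["g_leak"]);
  P.EL  = as<double>(par["E_leak"]);
  P.gNa = as<double>(par["g_Na"]);
  P.ENa = as<double>(par["E_Na"]);
  P.gK  = as<double>(par["g_K"]);
  P.EK  = as<double>(par["E_K"]);
  P.gM  = as<double>(par["g_M"]);
  P.Ee  = as<double>(par["V_rev_exc"]);
  P.Ei  = as<double>(par["V_rev_inh"]);
  P.thr = as<double>(par["spike_threshold"]);
  P.lockout = as<double>(par["lockout"]);
  P.guard = as<double>(par["guard"]);
  double v_t     = as<double>(par["V_T"]);
  double tau_max = as<double>(par["tau_max"]);
  double tau_s   = as<double>(par["tau_s"]);
  double Iext    = as<double>(par["I_ext_internal"]);     // uA/cm^2
  double g_jump_exc = as<double>(par["g_jump_exc"]);      // mS/cm^2
  double g_jump_inh = as<double>(par["g_jump_inh"]);
  double v0_lo = as<double>(par["init_v_lo"]);
  double v0_hi = as<double>(par["init_v_hi"]);

  const int n = n_neurons;
  const int nsteps = (int)std::llround(duration / dt);
  RateTabs T = build_tabs(v_t, tau_max);

  // stage decay factors for the synaptic conductances within one RK4 step
  const double dhalf = std::exp(-0.5 * dt / tau_s);
  const double dfull = dhalf * dhalf;

  std::vector<double> V(n), m(n), h(n), nn(n), p(n);
  std::vector<double> g(n, 0.0), Ge(n, 0.0), Gi(n, 0.0);
  std::vector<double> last_spike(n, 0.0), last_det(n, -1e9), Iextra(n, 0.0);

  // reproducible initial conditions: V uniform, gates at steady state
  std::mt19937 gen((unsigned)seed);
  std::uniform_real_distribution<double> unif(v0_lo, v0_hi);
  for (int i = 0; i < n; ++i) {
    V[i] = unif(gen);
    double x = (V[i] - T.vmin) * T.inv_dv;
    int k = (int)x; double w = x - k;
    const double* r0 = &T.tab[8 * k];
    const double* r1 = r0 + 8;
    double am = r0[0] + w * (r1[0] - r0[0]);
    double sm = r0[1] + w * (r1[1] - r0[1]);
    double ah = r0[2] + w * (r1[2] - r0[2]);
    double sh = r0[3] + w * (r1[3] - r0[3]);
    double an = r0[4] + w * (r1[4] - r0[4]);
    double sn = r0[5] + w * (r1[5] - r0[5]);
    double pq = r0[6] + w * (r1[6] - r0[6]);
    double pt = r0[7] + w * (r1[7] - r0[7]);
    m[i]  = am / sm;
    h[i]  = ah / sh;
    nn[i] = an / sn;
    p[i]  = pq / pt;
  }

  // controller
  bool ctl_on = as<bool>(control["enabled"]);
  IntegerVector ctl_targets = control["targets"];     // 0-based
  double trig   = as<double>(control["trigger_threshold"]);
  double Isup   = as<double>(control["I_sup_internal"]);
  double t_sup  = as<double>(control["t_sup"]);
  double cooldown = as<double>(control["cooldown"]);
  bool stim_active = false;
  double stim_off_t = 0.0, cooldown_until = -1.0;
  double sum_last = 0.0;               // sum of last-spike times (t_start = 0)
  double prev_meanT = 0.0;
  std::vector<double> ev_on, ev_off;

  // trace recording
  IntegerVector rec_idx = record["idx"];              // 0-based neuron ids
  int rec_every = as<int>(record["every"]);           // in steps; 0 = none
  int nrec = rec_idx.size();
  int nsamp = (rec_every > 0 && nrec > 0)
    ? ((nsteps + rec_every - 1) / rec_every) : 0;
  NumericMatrix trV(nrec, nsamp), trIM(nrec, nsamp), trG(nrec, nsamp);
  NumericVector trt(nsamp);
  int isamp = 0;

  std::vector<double> spk_t;
  std::vector<int> spk_id;
  // generous reservation (~40 Hz mean rate) avoids large mid-run reallocations
  size_t est = (size_t)(0.04 * n * duration) + 1024;
  spk_t.reserve(est);
  spk_id.reserve(est);
  std::vector<int> fired;
  fired.reserve(256);

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    if ((step & 8191) == 0) Rcpp::checkUserInterrupt();

    if (nsamp > 0 && step % rec_every == 0) {
      for (int r = 0; r < nrec; ++r) {
        int i = rec_idx[r];
        trV(r, isamp) = V[i];
        trIM(r, isamp) = P.gM * p[i] * (P.EK - V[i]);
        trG(r, isamp) = g[i];
      }
      trt[isamp] = t;
      ++isamp;
    }

    if (stim_active && t >= stim_off_t) {
      for (int k = 0; k < ctl_targets.size(); ++k) Iextra[ctl_targets[k]] = 0.0;
      stim_active = false;
      cooldown_until = stim_off_t + cooldown;
    }

    fired.clear();
    const bool has_stim = ctl_on && ctl_targets.size() > 0;
    double* __restrict Vp = V.data();
    double* __restrict mp = m.data();
    double* __restrict hp = h.data();
    double* __restrict np = nn.data();
    double* __restrict pp = p.data();
    double* __restrict Gep = Ge.data();
    double* __restrict Gip = Gi.data();
    double* __restrict gp = g.data();
    const double* __restrict Ixp = Iextra.data();
    for (int i = 0; i < n; ++i) {
      double Vi = Vp[i], mi = mp[i], hi = hp[i], ni = np[i], pi = pp[i];
      double Iin = has_stim ? Iext + Ixp[i] : Iext;
      double Ge0 = Gep[i], Gi0 = Gip[i];
      double k1V, k1m, k1h, k1n, k1p;
      deriv(T, P, Vi, mi, hi, ni, pi, Ge0, Gi0, Iin, k1V, k1m, k1h, k1n, k1p);
      double Geh = Ge0 * dhalf, Gih = Gi0 * dhalf;
      double k2V, k2m, k2h, k2n, k2p;
      deriv(T, P, Vi + 0.5 * dt * k1V, mi + 0.5 * dt * k1m, hi + 0.5 * dt * k1h,
            ni + 0.5 * dt * k1n, pi + 0.5 * dt * k1p, Geh, Gih, Iin,
            k2V, k2m, k2h, k2n, k2p);
      double k3V, k3m, k3h, k3n, k3p;
      deriv(T, P, Vi + 0.5 * dt * k2V, mi + 0.5 * dt * k2m, hi + 0.5 * dt * k2h,
            ni + 0.5 * dt * k2n, pi + 0.5 * dt * k2p, Geh, Gih, Iin,
            k3V, k3m, k3h, k3n, k3p);
      double Gef = Ge0 * dfull, Gif = Gi0 * dfull;
      double k4V, k4m, k4h, k4n, k4p;
      deriv(T, P, Vi + dt * k3V, mi + dt * k3m, hi + dt * k3h,
            ni + dt * k3n, pi + dt * k3p, Gef, Gif, Iin,
            k4V, k4m, k4h, k4n, k4p);
      double dt6 = dt / 6.0;
      double Vn = Vi + dt6 * (k1V + 2.0 * k2V + 2.0 * k3V + k4V);
      // gates clamped to [0,1] (RK4 can overshoot by a rounding margin)
      mp[i] = std::min(1.0, std::max(0.0, mi + dt6 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m)));
      hp[i] = std::min(1.0, std::max(0.0, hi + dt6 * (k1h + 2.0 * k2h + 2.0 * k3h + k4h)));
      np[i] = std::min(1.0, std::max(0.0, ni + dt6 * (k1n + 2.0 * k2n + 2.0 * k3n + k4n)));
      pp[i] = std::min(1.0, std::max(0.0, pi + dt6 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p)));
      // single guard: NaN fails the comparison too
      if (!(std::fabs(Vn) <= P.guard))
        stop("membrane potential diverged (neuron %d, step %d, t = %.3f ms)",
             i + 1, step + 1, t);
      if (Vn > P.thr && Vi <= P.thr && t + dt - last_det[i] >= P.lockout) {
        fired.push_back(i);
        last_det[i] = t + dt;
      }
      Vp[i] = Vn;
      // decay of the conductances and input sums, flushed to zero at 1e-30
      // so long silences never hit subnormal arithmetic
      double gg = gp[i] * dfull, ge = Ge0 * dfull, gi = Gi0 * dfull;
      gp[i]  = (gg < 1e-30) ? 0.0 : gg;
      Gep[i] = (ge < 1e-30) ? 0.0 : ge;
      Gip[i] = (gi < 1e-30) ? 0.0 : gi;
    }
    double tnew = t + dt;
    for (size_t s = 0; s < fired.size(); ++s) {
      int j = fired[s];
      double inc = is_exc[j] ? g_jump_exc : g_jump_inh;
      g[j] += inc;
      for (int q = tgt_ptr[j]; q < tgt_ptr[j + 1]; ++q) {
        int i = tgt_idx[q];
        if (is_exc[j]) Ge[i] += inc; else Gi[i] += inc;
      }
      sum_last += tnew - last_spike[j];
      last_spike[j] = tnew;
      spk_t.push_back(tnew);
      spk_id.push_back(j + 1);      // 1-based for R
    }

    if (ctl_on) {
      double meanT = tnew - sum_last / n;
      if (!stim_active && tnew >= cooldown_until &&
          prev_meanT <= trig && meanT > trig && ctl_targets.size() > 0) {
        for (int k = 0; k < ctl_targets.size(); ++k)
          Iextra[ctl_targets[k]] = Isup;
        stim_active = true;
        stim_off_t = tnew + t_sup;
        ev_on.push_back(tnew);
        ev_off.push_back(std::min(stim_off_t, duration));
      }
      prev_meanT = meanT;
    }
  }

  List traces = R_NilValue;
  if (nsamp > 0) {
    traces = List::create(_["t"] = trt, _["V"] = trV, _["I_M"] = trIM,
                          _["g"] = trG);
  }
  return List::create(
    _["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
    _["spike_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
    _["stim_on"] = NumericVector(ev_on.begin(), ev_on.end()),
    _["stim_off"] = NumericVector(ev_off.begin(), ev_off.end()),
    _["traces"] = traces);
}
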