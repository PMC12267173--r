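// Fixed-step network integrator for Hodgkin-Huxley neurons coupled by
// electrical (gap-junction) or delayed threshold-gated chemical synapses.
//
// Scheme: classic RK4 (or forward Euler) on the full 4N-dimensional state.
// The deterministic stimulus is supplied pre-sampled on the half-step grid
// so the RK4 substages see it at t, t+dt/2 and t+dt; the delayed presynaptic
// voltages and the per-step noise increment are held constant within a step
// (method-of-steps approximation).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// HH transition rates (1/ms); removable singularities of alpha_m (V = -40)
// and alpha_n (V = -55) evaluated by their analytic limits.
inline double alpha_m(double V) {
  double x = V + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
inline double beta_m(double V)  { return 4.0 * std::exp(-(V + 65.0) / 18.0); }
inline double alpha_h(double V) { return 0.07 * std::exp(-(V + 65.0) / 20.0); }
inline double beta_h(double V)  { return 1.0 / (std::exp(-(V + 35.0) / 10.0) + 1.0); }
inline double alpha_n(double V) {
  double x = V + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
inline double beta_n(double V)  { return 0.125 * std::exp(-(V + 65.0) / 80.0); }

struct HHP { double C, gNa, gK, gL, eNa, eK, eL; };

// Derivative of the whole network.  kind: 0 = ES, 1 = HS, 2 = RS.
// gate_cnt[i]: number of open chemical afferents of neuron i (fixed over
// the step, computed from delayed presynaptic voltages).
void derivs(int N,
            const std::vector<double>& V, const std::vector<double>& m,
            const std::vector<double>& h, const std::vector<double>& n,
            const HHP& P, int kind, double g, double vrev, bool rs_literal,
            const std::vector<double>& gate_cnt,
            const std::vector<int>& asrc, const std::vector<int>& adst,
            double iext, int stim,
            std::vector<double>& dV, std::vector<double>& dm,
            std::vector<double>& dh, std::vector<double>& dn)
{
  for (int i = 0; i < N; ++i) {
    const double Vi = V[i];
    double I = (i == stim) ? iext : 0.0;
    if (kind == 1) {
      I += g * gate_cnt[i];
    } else if (kind == 2) {
      const double drive = rs_literal ? (Vi - vrev) : (vrev - Vi);
      I += g * gate_cnt[i] * drive;
    }
    dV[i] = I;
    dm[i] = alpha_m(Vi) * (1.0 - m[i]) - beta_m(Vi) * m[i];
    dh[i] = alpha_h(Vi) * (1.0 - h[i]) - beta_h(Vi) * h[i];
    dn[i] = alpha_n(Vi) * (1.0 - n[i]) - beta_n(Vi) * n[i];
  }
  if (kind == 0) {
    const int na = (int) asrc.size();
    for (int a = 0; a < na; ++a)
      dV[adst[a]] += g * (V[asrc[a]] - V[adst[a]]);
  }
  for (int i = 0; i < N; ++i) {
    const double Vi = V[i];
    const double gna = P.gNa * m[i] * m[i] * m[i] * h[i];
    const double n2 = n[i] * n[i];
    const double ionic = gna * (P.eNa - Vi) + P.gK * n2 * n2 * (P.eK - Vi) +
      P.gL * (P.eL - Vi);
    dV[i] = (dV[i] + ionic) / P.C;
  }
}

} // namespace

// [[Rcpp::export]]
List sim_core_cpp(NumericVector v0, NumericVector m0, NumericVector h0,
                  NumericVector n0,
                  IntegerVector arc_src, IntegerVector arc_dst,
                  int syn_kind, double g, double vthresh, double vrev,
                  bool rs_literal, int delay_steps,
                  NumericVector iext_half, NumericVector iext_step,
                  int stim_node,
                  NumericVector hh, double dt, int nsteps,
                  bool use_rk4, int record_stride)
{
  const int N = v0.size();
  const int narcs = arc_src.size();
  if (iext_half.size() != 2 * nsteps + 1)
    stop("internal error: stimulus must be sampled on the half-step grid");
  if (iext_step.size() != nsteps && iext_step.size() != 0)
    stop("internal error: per-step stimulus must have one value per step");
  const bool have_step_noise = iext_step.size() == nsteps;
  HHP P { hh[0], hh[1], hh[2], hh[3], hh[4], hh[5], hh[6] };

  std::vector<double> V(v0.begin(), v0.end()), m(m0.begin(), m0.end()),
    h(h0.begin(), h0.end()), n(n0.begin(), n0.end());
  std::vector<int> asrc(narcs), adst(narcs);
  for (int a = 0; a < narcs; ++a) {
    asrc[a] = arc_src[a] - 1;  // to 0-based
    adst[a] = arc_dst[a] - 1;
  }
  const int stim = stim_node - 1;

  const bool chem = (syn_kind == 1 || syn_kind == 2);
  const int hlen = delay_steps + 1;
  std::vector<double> hist;
  int head = 0;
  if (chem) {
    hist.resize((size_t) hlen * N);
    for (int s = 0; s < hlen; ++s)
      for (int i = 0; i < N; ++i) hist[(size_t) s * N + i] = V[i];
  }

  const int nrec = nsteps / record_stride + 1;
  NumericMatrix Vrec(N, nrec);
  for (int i = 0; i < N; ++i) Vrec(i, 0) = V[i];
  int rec = 1;

  std::vector<double> gate_cnt(N, 0.0);
  std::vector<double> k1V(N), k1m(N), k1h(N), k1n(N), k2V(N), k2m(N), k2h(N),
    k2n(N), k3V(N), k3m(N), k3h(N), k3n(N), k4V(N), k4m(N), k4h(N), k4n(N),
    tV(N), tm(N), th(N), tn(N);

  for (int k = 0; k < nsteps; ++k) {
    if (chem) {
      std::fill(gate_cnt.begin(), gate_cnt.end(), 0.0);
      const int dslot = (head + 1) % hlen;  // step k - delay_steps
      const double* Vdel = &hist[(size_t) dslot * N];
      for (int a = 0; a < narcs; ++a)
        if (Vdel[asrc[a]] > vthresh) gate_cnt[adst[a]] += 1.0;
    }
    const double nz = have_step_noise ? iext_step[k] : 0.0;
    const double i0 = iext_half[2 * k] + nz;
    const double i1 = iext_half[2 * k + 1] + nz;
    const double i2 = iext_half[2 * k + 2] + nz;

    if (use_rk4) {
      derivs(N, V, m, h, n, P, syn_kind, g, vrev, rs_literal, gate_cnt,
             asrc, adst, i0, stim, k1V, k1m, k1h, k1n);
      for (int i = 0; i < N; ++i) {
        tV[i] = V[i] + 0.5 * dt * k1V[i]; tm[i] = m[i] + 0.5 * dt * k1m[i];
        th[i] = h[i] + 0.5 * dt * k1h[i]; tn[i] = n[i] + 0.5 * dt * k1n[i];
      }
      derivs(N, tV, tm, th, tn, P, syn_kind, g, vrev, rs_literal, gate_cnt,
             asrc, adst, i1, stim, k2V, k2m, k2h, k2n);
      for (int i = 0; i < N; ++i) {
        tV[i] = V[i] + 0.5 * dt * k2V[i]; tm[i] = m[i] + 0.5 * dt * k2m[i];
        th[i] = h[i] + 0.5 * dt * k2h[i]; tn[i] = n[i] + 0.5 * dt * k2n[i];
      }
      derivs(N, tV, tm, th, tn, P, syn_kind, g, vrev, rs_literal, gate_cnt,
             asrc, adst, i1, stim, k3V, k3m, k3h, k3n);
      for (int i = 0; i < N; ++i) {
        tV[i] = V[i] + dt * k3V[i]; tm[i] = m[i] + dt * k3m[i];
        th[i] = h[i] + dt * k3h[i]; tn[i] = n[i] + dt * k3n[i];
      }
      derivs(N, tV, tm, th, tn, P, syn_kind, g, vrev, rs_literal, gate_cnt,
             asrc, adst, i2, stim, k4V, k4m, k4h, k4n);
      const double w = dt / 6.0;
      for (int i = 0; i < N; ++i) {
        V[i] += w * (k1V[i] + 2.0 * k2V[i] + 2.0 * k3V[i] + k4V[i]);
        m[i] += w * (k1m[i] + 2.0 * k2m[i] + 2.0 * k3m[i] + k4m[i]);
        h[i] += w * (k1h[i] + 2.0 * k2h[i] + 2.0 * k3h[i] + k4h[i]);
        n[i] += w * (k1n[i] + 2.0 * k2n[i] + 2.0 * k3n[i] + k4n[i]);
      }
    } else {  // forward Euler
      derivs(N, V, m, h, n, P, syn_kind, g, vrev, rs_literal, gate_cnt,
             asrc, adst, i0, stim, k1V, k1m, k1h, k1n);
      for (int i = 0; i < N; ++i) {
        V[i] += dt * k1V[i]; m[i] += dt * k1m[i];
        h[i] += dt * k1h[i]; n[i] += dt * k1n[i];
      }
    }

    for (int i = 0; i < N; ++i) {
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > 150.0 ||
          !std::isfinite(m[i]) || !std::isfinite(h[i]) || !std::isfinite(n[i]))
        stop("divergence at neuron %d, t = %.4f ms", i + 1, (k + 1) * dt);
    }

    if (chem) {
      head = (head + 1) % hlen;
      double* slot = &hist[(size_t) head * N];
      for (int i = 0; i < N; ++i) slot[i] = V[i];
    }

    if ((k + 1) % record_stride == 0 && rec < nrec) {
      for (int i = 0; i < N; ++i) Vrec(i, rec) = V[i];
      ++rec;
    }
  }

  return List::create(_["V"] = Vrec,
                      _["final"] = List::create(_["v"] = wrap(V), _["m"] = wrap(m),
                                                _["h"] = wrap(h), _["n"] = wrap(n)));
}
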