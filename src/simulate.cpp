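#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Fixed-step RK2 (midpoint) integration of a conductance-based E-I network of
// leaky integrate-and-fire neurons.  Synaptic conductances follow a delayed
// bi-exponential kernel, realised as two exponential state variables per
// neuron and synapse class driven by impulses from a latency ring buffer;
// this is algebraically identical to convolving each presynaptic spike train
// with the kernel, but O(N) per step.  Neurons 0..nE-1 are excitatory,
// nE..N-1 inhibitory.  All times in ms.
//
// External drive: the KO independent Poisson sources per neuron are pooled
// network-wide (superposition) into one Poisson count per step, with events
// assigned to neurons uniformly at random.
//
// Refractoriness: after a spike V is clamped at Vreset for the refractory
// period while the conductance states keep integrating inputs.
//
// [[Rcpp::export(name = ".simulate_ei_cpp")]]
List simulate_ei_cpp(int nE, int nI,
                     IntegerVector out_ptr, IntegerVector out_idx,
                     List par, IntegerVector record, int seed) {
  const int N = nE + nI;
  const double gEO = par["g_EO"], gIO = par["g_IO"];
  const double gEE = par["g_EE"], gIE = par["g_IE"];
  const double gEI = par["g_EI"], gII = par["g_II"];
  const double EE = par["E_E"], EI = par["E_I"];
  const double tauE = par["tau_E"], tauI = par["tau_I"];
  const double VL = par["V_L"], theta = par["theta"], Vreset = par["V_reset"];
  const double trpE = par["t_rp_E"], trpI = par["t_rp_I"];
  const double taul = par["tau_l"], taur = par["tau_r"];
  const double taude = par["tau_de"], taudi = par["tau_di"];
  const double dt = par["dt"];
  const double duration_ms = par["duration_ms"];
  const double discard_ms = par["discard_ms"];
  const double KO = par["K_O"], fex = par["f_ex"];
  const bool current_based = as<bool>(par["current_based"]);
  const double Vmean = par["V_mean"];
  const double clampGE = par["clamp_G_E"], clampGI = par["clamp_G_I"];

  const int S = (int) std::lround(duration_ms / dt);
  const int L = std::max(1, (int) std::lround(taul / dt));
  const int trpE_steps = (int) std::lround(trpE / dt);
  const int trpI_steps = (int) std::lround(trpI / dt);

  const double dEd = std::exp(-dt / taude), dId = std::exp(-dt / taudi);
  const double dR = std::exp(-dt / taur);
  const double invDE = 1.0 / (taude - taur), invDI = 1.0 / (taudi - taur);

  std::mt19937_64 rng((uint64_t) seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double lambda_tot = N * KO * fex * dt * 1e-3;  // pooled events/step
  std::poisson_distribution<int> pois(lambda_tot > 0 ? lambda_tot : 1.0);

  std::vector<double> V(N), xEd(N, 0.0), xEr(N, 0.0), xId(N, 0.0), xIr(N, 0.0);
  std::vector<int> refr(N, 0);
  for (int i = 0; i < N; ++i) V[i] = VL + (theta - VL) * unif(rng);

  std::vector<double> pendE((size_t) L * N, 0.0), pendI((size_t) L * N, 0.0);

  std::vector<int> sp_n;
  std::vector<double> sp_t;
  sp_n.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  const int nrec = record.size();
  const int S_keep = (int) std::lround((duration_ms - discard_ms) / dt);
  NumericMatrix trV, trGE, trGI;
  NumericVector trT;
  std::vector<int> reccol(N, -1);
  if (nrec > 0) {
    trV = NumericMatrix(S_keep, nrec);
    trGE = NumericMatrix(S_keep, nrec);
    trGI = NumericMatrix(S_keep, nrec);
    trT = NumericVector(S_keep);
    for (int rix = 0; rix < nrec; ++rix) reccol[record[rix] - 1] = rix;
  }

  const double out_dur = duration_ms - discard_ms;

  for (int step = 0; step < S; ++step) {
    const int slot = step % L;
    const int dslot = (step + L) % L;  // == slot: arrivals L steps ahead
    double *pe = &pendE[(size_t) slot * N];
    double *pi = &pendI[(size_t) slot * N];

    // decay kernel states, deliver impulses whose latency elapses now
    for (int i = 0; i < N; ++i) {
      xEd[i] = xEd[i] * dEd + pe[i];
      xEr[i] = xEr[i] * dR + pe[i];
      xId[i] = xId[i] * dId + pi[i];
      xIr[i] = xIr[i] * dR + pi[i];
      pe[i] = 0.0;
      pi[i] = 0.0;
    }

    // schedule external Poisson arrivals (latency tau_l ahead)
    if (lambda_tot > 0) {
      int k = pois(rng);
      for (int e = 0; e < k; ++e) {
        int i = (int) (unif(rng) * N);
        if (i >= N) i = N - 1;
        pendE[(size_t) dslot * N + i] += (i < nE) ? gEO : gIO;
      }
    }

    const double t_end = (step + 1) * dt;
    for (int i = 0; i < N; ++i) {
      const bool isE = i < nE;
      const double tau = isE ? tauE : tauI;
      const double GE = tau * (xEd[i] - xEr[i]) * invDE + clampGE;
      const double GI = tau * (xId[i] - xIr[i]) * invDI + clampGI;

      bool spiked = false;
      if (refr[i] > 0) {
        --refr[i];
        V[i] = Vreset;
      } else {
        double a, b;
        if (current_based) {
          a = 1.0 / tau;
          b = (VL + GE * (EE - Vmean) + GI * (EI - Vmean)) / tau;
        } else {
          a = (1.0 + GE + GI) / tau;
          b = (VL + GE * EE + GI * EI) / tau;
        }
        const double v0 = V[i];
        const double adt = a * dt;
        double v1;
        if (adt < 0.5) {
          // RK2 midpoint (conductances piecewise-constant over the step)
          const double vmid = v0 + 0.5 * dt * (b - a * v0);
          v1 = v0 + dt * (b - a * vmid);
        } else {
          // stiff high-conductance regime (tau_eff approaching dt, where
          // explicit RK2 loses stability): exact update of the linear
          // membrane equation with frozen conductances
          const double vinf = b / a;
          v1 = vinf + (v0 - vinf) * std::exp(-adt);
        }
        if (!std::isfinite(v1) || v1 < -1e6 || v1 > 1e6)
          stop("membrane potential diverged at step %d (neuron %d)", step, i + 1);
        if (v1 >= theta) {
          spiked = true;
          v1 = Vreset;
          refr[i] = isE ? trpE_steps : trpI_steps;
          const double t_out = t_end - discard_ms;
          if (t_out >= 0.0 && t_out < out_dur) {
            sp_n.push_back(i + 1);
            sp_t.push_back(t_out);
          }
          // propagate to postsynaptic targets after the synaptic latency
          for (int m = out_ptr[i]; m < out_ptr[i + 1]; ++m) {
            const int j = out_idx[m];
            if (isE)
              pendE[(size_t) dslot * N + j] += (j < nE) ? gEE : gIE;
            else
              pendI[(size_t) dslot * N + j] += (j < nE) ? gEI : gII;
          }
        }
        V[i] = v1;
      }
      (void) spiked;

      if (nrec > 0 && t_end > discard_ms) {
        const int row = step - (S - S_keep);
        const int c = reccol[i];
        if (c >= 0 && row >= 0 && row < S_keep) {
          trV(row, c) = V[i];
          trGE(row, c) = GE;
          trGI(row, c) = GI;
        }
        if (i == 0 && row >= 0 && row < S_keep) trT[row] = t_end - discard_ms;
      }
    }
  }

  List out = List::create(_["neuron"] = wrap(sp_n), _["time"] = wrap(sp_t));
  if (nrec > 0) {
    out["trace_time"] = trT;
    out["trace_V"] = trV;
    out["trace_GE"] = trGE;
    out["trace_GI"] = trGI;
  }
  return out;
}
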