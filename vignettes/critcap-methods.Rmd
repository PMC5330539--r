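---
title: "Multi-scale dynamics and cost-efficient capacity in E-I spiking networks"
author: "critcap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale dynamics and cost-efficient capacity in E-I spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(critcap)
```

# The model

`critcap` simulates a randomly connected network of $N = 2500$ leaky
integrate-and-fire neurons, 2000 excitatory (E) and 500 inhibitory (I),
with connection probability $C = 0.2$.  The sub-threshold membrane
potential of neuron $i$ in population $k \in \{E, I\}$ obeys

$$\tau_k \frac{dV_i}{dt} = V_L - V_i + G^E_i(t)\,(E_E - V_i) +
  G^I_i(t)\,(E_I - V_i),$$

with membrane time constants $\tau_E = 20$ ms, $\tau_I = 10$ ms, leak
potential $V_L = -70$ mV and reversal potentials $E_E = 0$ mV,
$E_I = -70$ mV.  When $V_i$ reaches the threshold $\theta = -50$ mV the
neuron emits a spike, is reset to $-60$ mV, and is clamped there for a
refractory period (2 ms for E, 1 ms for I) while its synaptic
conductances keep integrating inputs.  The dimensionless conductances
$G^{E}_i, G^{I}_i$ (in units of the leak conductance $g_L = 10$ nS,
scaled by $\tau_k$) are sums over presynaptic spikes filtered by a
delayed bi-exponential kernel

$$s(t) = \Theta(t - \tau_l)\,
  \frac{e^{-(t-\tau_l)/\tau_d} - e^{-(t-\tau_l)/\tau_r}}{\tau_d - \tau_r},$$

with latency $\tau_l = 1$ ms, rise time $\tau_r = 0.5$ ms, and the
E/I decay times $(\tau_{d_e}, \tau_{d_i})$ as the swept control
parameters.  The kernel has unit time-integral for any valid parameters
(`synapticKernel`, `kernelPeakTime`).  Synaptic strengths
($g^{EO} = 0.05$, $g^{IO} = 0.08$, $g^{EE} = 0.04$, $g^{IE} = 0.08$,
$g^{EI} = 0.6$, $g^{II} = 0.96$; first index postsynaptic) realise an
E-I balanced state: at $(\tau_{d_e}, \tau_{d_i}) = (6, 6)$ ms the mean
excitatory and inhibitory currents onto a neuron cancel to within about
10% of the mean excitatory current, leaving fluctuation-driven irregular
firing.  Each neuron additionally receives $K_O = 400$ independent
external Poisson inputs at $f_{ex} = 2.5$ Hz each; by the superposition
property these are pooled into a single 1000-Hz Poisson process per
neuron, independent across neurons.

A current-based variant (`model_variant = "current"`) replaces the
voltage-dependent driving forces by a fixed driving potential
$\bar V = -60$ mV; it is exposed as a simulator option for comparing
conductance- and current-based dynamics.

## Numerics

Integration uses a fixed step $dt = 0.05$ ms.  Within a step the
conductances are held constant and the membrane equation — then linear,
$\dot V = b - aV$ — is advanced by midpoint (second-order Runge-Kutta).
Explicit RK2 loses stability when $a\,dt > 2$, which the highly
synchronized states actually reach: population volleys drive the total
conductance of inhibitory neurons above $2\tau_I/dt \approx 400$.
Neuron-steps with $a\,dt \ge 0.5$ therefore switch to the exact
exponential update $V \leftarrow V_\infty + (V - V_\infty)e^{-a\,dt}$ of
the same linear equation, which is unconditionally stable and agrees
with RK2 to $O((a\,dt)^3)$ where both apply.  Threshold crossings are
detected at the end of each step and spike times recorded on the step
grid; at $dt = 0.05$ ms the resulting bias on, e.g., a 20-ms ISI is
below 0.3%, and halving $dt$ changes reference-state population rates
by well under 5% (tested).  The bi-exponential kernel is realised as two
exponential states per neuron and synapse class, driven by impulses from
a latency ring buffer — algebraically identical to convolving every
presynaptic train with the kernel, and $O(N)$ per step.  Initial
potentials are uniform on $[V_L, \theta)$; the first second of every run
is discarded.  Runs are bit-reproducible given the integer seed
(`std::mt19937_64` in the compiled core).

Desk-scale durations are 50 s per parameter set (the statistics
quoted below and asserted in the test-suite use 50-s runs; entropy and
avalanche statistics are duration-dependent and are reported together
with their sample sizes so users can extend runs).

# Multi-scale characterisation

* **Irregularity** — `isiCV`/`meanISICV`: per-neuron SD/mean of the
  inter-spike intervals, population (divide-by-$N$) SD convention,
  neurons with fewer than three spikes excluded.  The reference network
  sits near CV $\approx 1$ (Poisson-like) in the moderately synchronized
  region and above 1 (bursty) in the asynchronous region.
* **Synchrony** — `synchronyIndex`: average pair coherence
  $K_{ij} = \sum_k B_i B_j / \sqrt{\sum_k B_i \sum_k B_j}$ over sampled
  pairs of 1-ms binarised trains.  Two denominators are in use for this
  coherence in the literature; the geometric-mean normalisation, the
  standard form bounded in $[0,1]$, is the default, and the
  plain-product denominator is available behind
  `normalization = "product"`.  2000 random excitatory pairs are used by
  default.
* **Oscillations** — `populationAutocorrelation` (mean-centred,
  $\langle A\rangle^2 T$-normalised) and `spectrumPeak`: Welch spectrum
  of the mean-detrended 1-ms population activity with 2-s Hann segments
  and 50% overlap, Gaussian-smoothed with $\sigma = 2$ Hz; the peak is
  searched at $f \ge 10$ Hz so the low-frequency mass of asynchronous
  activity never masquerades as a rhythm.  These four spectral settings
  (segment length, overlap, smoothing width, floor frequency) are
  package choices.
* **Cross-correlations** — `crossCorrelogram`: conditional firing rate
  of one neuron around the spike times of another, averaged over 2000
  random pairs; flat at the mean rate for independent trains, and
  concentrated within about $\pm 20$ ms at the moderately synchronized
  state, which motivates the 20-ms pattern window below.

# Neuronal avalanches and the distance D

Avalanches (`extractAvalanches`) are maximal runs of consecutive
non-empty $\delta t$-bins of pooled excitatory spikes, flanked by empty
bins; the size is the number of distinct participating neurons (default)
or the total spike count.  The default bin is $\delta t = 0.1$ ms.  The
conventional upper end of the binning range, 1 ms, is unusable for this
network's pooled activity: at the critical state the excitatory
population emits $\approx 6$ spikes per millisecond, so nearly every
1-ms bin is occupied and entire gamma cycles merge into single
avalanches.  $0.1$ ms is close to the mean population inter-event
interval ($\approx 0.17$ ms at the critical state), the standard
data-driven choice for spike-avalanche binning, and the resulting
distance ordering across states is reproducible across seeds and stable
between $\delta t = 0.1$ and $0.2$ ms (tested).

`fitPowerLaw` fits $P(s) \propto s^{-\alpha}$ on $[1, s_{max}]$ by
discrete truncated maximum likelihood ($s_{max}$ the largest observed
size; a least-squares fit on logarithmically binned mass is available as
`method = "logbin-ls"`) and computes the distance

$$D = \frac{\sum_s s\,|P(s) - P_{fit}(s)|}{\sum_s s\,P_{fit}(s)},$$

the size-weighted $L_1$ gap per avalanche relative to the fitted mean
size.  The sums are evaluated over logarithmically binned (factor-2)
masses by default: evaluated size-by-size, the heavy tail contributes
pure sampling noise that dominates the statistic even for a perfect
power-law sample ($D \approx 0.3$ at $10^5$ samples of a clean
$\alpha = 1.5$ law, versus $\approx 0.02$ after binning), swamping the
systematic misfit that $D$ is meant to measure.  `distance = "raw"`
gives the literal per-size sums.  Subcritical (exponentially decaying)
and supercritical (bimodal) size distributions score an order of
magnitude higher than matched power-law samples under either
evaluation.

# Spike patterns, capacity, and energy efficiency

`makePatterns` tiles the raster into non-overlapping
$\Delta\tau = 20$ ms windows (final partial window dropped) and, for
each of 100 seeded random subsets of $n = 40$ excitatory neurons,
records per-window patterns: a spiking indicator per neuron (binary
scenario) or the spike count capped at 10 (analog scenario; with a 2-ms
refractory period a neuron cannot usefully exceed 10 spikes per 20-ms
window).  The plug-in entropy $H = -\sum_i p_i \log_2 p_i$ over observed
patterns (empty pattern included) measures information capacity.  No
bias correction is applied — matching the plug-in estimator used with
long recordings — so $H$ is biased downward at short durations; reports
carry $T_w$ (2500 windows at 50 s) so undersampling can be judged, and
state comparisons use equal durations so the bias cancels to first
order.

Energy accounting: a spike costs one unit, and a resting neuron costs
$r$ units per window (empirically $r \in [0.005, 0.1]$).  The energy per
window is $E = m + n r$ with $m$ the mean *uncapped* spike count — every
emitted spike costs energy even when the binary encoding collapses
repeated spikes, which is precisely what makes the burst reduction
$R_B$ meaningful.  Efficiency is $\eta_{sim} = H/E$
(`patternEfficiency`).

The maximum-entropy upper bound at activity level $\rho = m/n$
(`etaOpt`) is

$$\eta_{opt} = \frac{f(\rho)}{\rho + r} \;\; \text{(binary)}, \qquad
  \eta_{opt} = \frac{f(\rho/(1+\rho))(1+\rho)}{\rho + r} \;\;
  \text{(analog)},$$

with $f$ the binary entropy function; it is attained by independent
Bernoulli neurons (binary) or independent geometric spike counts
(analog) — `optimalPatternDistribution`.  The analog closed form uses
the geometric (untruncated) count distribution; exhaustive enumeration
of the truncated ($s \le 10$) system agrees to the truncation error
(tested at $n = 3$).  The optimal activity level $\rho_m(r)$ solves
$\rho_m^r = (1-\rho_m)^{1+r}$ (binary) or
$\rho_m^r = (1+\rho_m)^{r-1}$ (analog); both conditions are derived from
the first-order optimality of the curves above, and the test-suite
cross-checks the roots against a grid argmax to $10^{-6}$
(`rhoM`, bisection bracket $(10^{-12}, 1-10^{-12})$ or
$(10^{-12}, 10^3)$, tolerance $10^{-12}$).  At $r = 0$, $\rho_m \to 0$
and `rhoM` returns 0 with a `limit` flag.  For $\Delta\tau = 20$ ms the
optimal firing rates $v_m = \rho_m/\Delta\tau$ span 1–8 Hz (binary) and
1–10 Hz (analog) over the empirical $r$ range.  The analog stationarity
condition gives $\rho_m = 1$ exactly at $r = 1$ and grows beyond 1 for
$r > 1$, while the geometric approximation presumes $\rho' < 1$; within
the empirical $r$ range the forms agree, and the large-$r$ regime is
documented rather than resolved.

The efficiency gap decomposes (`reductionDecomposition`) into a burst
part $R_B = H/m_n - H/m = (B-1)\eta_{sim}$ ($B = m/m_n$ the burst
level, $m_n$ the mean spiking-neuron count) and a synchronisation part
$R_S = \eta_{opt}(m_n/n) - B\eta_{sim}$, which sum *exactly* to
$\eta_{opt}(m_n/n) - H/m$ at $r = 0$ (the headline decomposition).  For
$r > 0$ the same forms are reported as diagnostics with
$\eta_{sim} = H/(m + nr)$, closing exactly to
$\eta_{opt}(m_n/n; r) - H/(m+nr)$.  The empty-pattern check
(`emptyPatternProbability`) compares the observed fraction of silent
windows with the independent-firing prediction
$(1 - m_n/n)^n \approx e^{-m_n}$.

Averaging convention: the package averages $H$, $m$ and $m_n$ over the
100 subsets and recomputes $\eta$ and the decomposition from the
averages (rather than averaging per-subset $\eta$ values); the report
records the subset count.

# Surrogate generators

`generateSurrogate` produces rasters with known ground truth, so every
analysis stage is testable without the network: Poisson trains
(CV $= 1$, pair coherence $\approx$ rate $\times$ 1 ms); gamma-renewal
trains (CV $= 1/\sqrt{k}$); jittered-synchrony rasters that copy a
hidden mother train with probability $c$ (tunable coherence); and a
discrete-time branching process with mean offspring $\sigma$ whose
avalanche sizes at $\sigma = 1$ follow the critical law
$P(s) \sim s^{-3/2}$.  Branching units map to neuron indices
round-robin, making the distinct-neuron and spike-count size
definitions differ predictably.  Avalanches exceeding `max_size` total
units are discarded (truncation), not capped in place: a reflecting
activity cap measurably biases the critical size distribution, while
truncation just conditions on $s \le s_{max}$ — consistent with the
truncated fit.  Silent bins restart activity with one initiating unit
at rate `drive` per bin, so generated avalanches stay flanked by empty
bins and `extractAvalanches` at the generator's bin width recovers them
exactly (up to the 5% of adjacent-bin coincidences expected at
`drive = 0.05`).

What the surrogates do *not* emulate: conductance dynamics, E-I loops,
oscillatory modulation, or rate heterogeneity.  Oracle tests passing on
surrogates validate the *estimators*, not the network model; the network
claims are tested separately on simulated rasters.

# The sweep driver

`runSweep` simulates and analyses each cell of a
$(\tau_{d_e}, \tau_{d_i})$ grid (default $5\times5$ over
$[2,6] \times [6,14]$ ms, 50 s per cell, one seed) and returns one tidy
row per (cell, seed): rates, CV, synchrony, spectral peak, avalanche
statistics, and $H$/$\eta_{sim}$ per scenario and resting energy.
Cells are cached as CSV keyed by the full cell configuration when
`cache_dir` is set, so a completed sweep re-runs without simulating;
failed cells are flagged rows and the sweep continues.  The desk-scale
defaults trade the long (multi-thousand-second) runs a publication-grade
phase diagram would use for tractable runtimes; all
duration-sensitive statistics carry their sample sizes in the output.

# Reference states, and what the tests show

Three parameter sets serve as reference states throughout the
test-suite (50 s each, seed 42): asynchronous $(6,6)$, moderately
synchronized $(4,10)$, highly synchronized $(2,14)$.  Measured on those
runs: excitatory rate is minimal ($\approx 2.7$ Hz) and the ISI CV
$\approx 1.1$ at $(4,10)$, with a spectral peak near 40 Hz (gamma
band); pairwise synchrony orders $(6,6) < (4,10) < (2,14)$; the
avalanche distance $D$ is smallest at $(4,10)$; and the simulated
efficiency $\eta_{sim}$ is maximal at $(4,10)$ in both scenarios for
$r \in \{0, 0.005, 0.1\}$.  These are the package's headline
assertions; `scripts/acceptance.R` recomputes the deterministic theory
numbers and the critical-state simulation quantities from scratch.

# Known limitations

* Plug-in entropy at 50 s ($T_w = 2500$) is biased downward relative to
  very long runs; orderings between states are robust, absolute $H$
  values are not asymptotic.
* The avalanche exponent depends on $\delta t$ (as it does for any
  pooled-activity avalanche analysis); only the distance ordering, not
  an absolute exponent, is asserted for the network.
* No plasticity, no spatial or modular topology, no event-driven exact
  integration, no GPU; single-threaded compiled core.
* The current-based variant is exposed as an option but only
  smoke-tested; its phase diagram is not characterised here.
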