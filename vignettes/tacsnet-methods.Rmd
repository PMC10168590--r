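---
title: "Methods: LIF networks, tACS entrainment and soft-bound STDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LIF networks, tACS entrainment and soft-bound STDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacsnet)
```

`tacsnet` simulates how weak sinusoidal stimulation — the kind delivered by
transcranial alternating current stimulation (tACS) — interacts with
spike-timing-dependent plasticity (STDP) in networks of leaky
integrate-and-fire (LIF) neurons whose membrane time constants (MTCs) are
heterogeneous. The central scientific claim the package lets you reproduce
is that a *mismatch* in timescales between connected neurons, combined with
periodic entrainment, gives stimulation directional control over synaptic
weights: synapses onto slower cells tend to potentiate, synapses onto faster
cells tend to depress, and the effect disappears when all cells share one
timescale.

## Membrane model

Each neuron follows the stochastic LIF equation

$$\tau_m \frac{dv}{dt} = (V_{rest} - v) + I_\zeta + I_{syn} + I_s,$$

with threshold $v_{thr}$, reset to $V_{rest}$, and an absolute refractory
period $\tau_{ref}$ during which the membrane is clamped at the reset value
and all inputs are ignored. Defaults follow the study's parameter tables:
$V_{rest} = -60$ mV (jittered per neuron by $\pm 0.2$ mV in networks, reused
for reset), $v_{thr} = -54$ mV, $\tau_{ref} = 2$ ms. The stimulation current
is $I_s = A_s \sin(2\pi \omega_s t + \theta)$, applied identically to every
neuron inside the stimulation window — the model deliberately abstracts away
electric-field physics (skull shunting, dendritic orientation), so $A_s$ is
an *effective* somatic amplitude in mV.

Integration uses the Euler–Maruyama scheme at $dt = 0.1$ ms (configurable):

$$\Delta v = \frac{dt}{\tau_m}\left(V_{rest} - v + \mu + I_{syn} + I_s\right)
          + \frac{\sigma}{\tau_m}\sqrt{dt}\,\xi, \qquad \xi \sim N(0,1).$$

The white-noise input $I_\zeta$ thus enters like a current with mean $\mu$
and intensity $\sigma$ (mV), both divided by $\tau_m$ — the stationary
membrane fluctuation is $\sigma/\sqrt{2\tau_m}$, so *faster cells are
noisier and more excitable*. This convention is fixed by two analytic
oracles that the test suite checks directly: the zero-input solution
$v(t) = V_{rest} + (v_0 - V_{rest})e^{-t/\tau_m}$ (with first-order
convergence in $dt$), and the deterministic suprathreshold period
$T = \tau_{ref} + \tau_m \ln\!\frac{\Delta I}{\Delta I - (v_{thr}-V_{rest})}$.
A spike is recorded when the updated potential reaches threshold; it is
stamped at the end of the step, and no neuron can fire twice within
$\tau_{ref}$.

A consequence worth stating explicitly: because the stationary noise
amplitude scales as $1/\sqrt{\tau_m}$ while the mean potential sits a fixed
0.5 mV below threshold, the firing rate falls steeply and *convexly* with
$\tau_m$. A cell at the 10 ms centre of the network's MTC distribution fires
near the 5 Hz operating point, and the population *median* sits there too,
but the Gaussian(10, 3) distribution's fast tail fires far above it, so the
population *mean* rate lands noticeably higher. The acceptance script
reports both the mean and the median for the sham network so this property
is visible rather than hidden.

## Synapses

Presynaptic spikes reach their targets after an axonal delay (fixed 0.5 ms
in the two-neuron motif; uniform in [0.5, 1] ms in networks) and produce a
double-exponential conductance transient

$$S(s) \propto e^{-s/\tau_d} - e^{-s/\tau_r}, \qquad s \ge 0,$$

peak-normalised to 1 so that the synaptic weight $g$ is the peak
conductance (or the peak current, below). Rise/decay constants are
0.5/3 ms for AMPA and 0.5/5 ms for GABA$_a$. In the population networks the
drive is conductance-based,

$$I_{syn,i}(t) = \sum_j g_{ij}\, S(t - t^{sp}_j - t_d)\,(E_{syn} - v_i),$$

with $E_{syn} = 0$ mV (AMPA) and $-85$ mV (GABA$_a$), so excitation
depolarises and inhibition hyperpolarises at physiological potentials. The
two-neuron motif instead uses current-based synapses (weight in mV),
reconciling its parameter table (a 0.1 mV baseline kick with no reversal
potential) with the population tables. The engine implements the kernels
with per-neuron exponential accumulators and a delay ring buffer — exact,
not truncated — and the tests verify the accumulator drive against direct
kernel summation to $10^{-9}$ on small fixtures, in both modes.

Delays are applied uniformly to excitatory and inhibitory synapses. The
engine delivers a spike's conductance using the weight at emission time.

## Plasticity

Plastic synapses (E→E, E→I and I→E; I→I is static) follow a symmetric
soft-bound Hebbian STDP rule in terms of the pre/post spike-time difference
$\Delta T = t_{post} - t_{pre}$:

$$\Delta g = \begin{cases}
  +A_+\,(1 - g/g_{max})\,e^{-\Delta T/\gamma_+}, & \Delta T > 0,\\[2pt]
  -A_-\,(g/g_0)\,e^{\Delta T/\gamma_-}, & \Delta T < 0,
\end{cases}$$

with $A_+ = 2A_- = 0.02$, $\gamma_\pm = 10$ ms, and hard bounds
$g_{min} = 0.01\,g_0$, $g_{max} = 2\,g_0$ enforced after every update.
Three implementation decisions matter:

* **Units.** $A_\pm$ are dimensionless *rates*: the rule operates on the
  baseline-normalised weight $g/g_0$, so one strong pairing moves a synapse
  by about 1% of its baseline regardless of whether that baseline is 0.1 mV
  (pair motif) or $5\times10^{-5}$ a.u. (network). Applying $A_\pm$ as
  absolute weight increments would exceed the network's entire weight range
  in a single pairing and turn every synapse into a two-state flip-flop —
  destroying the gradual, direction-resolved weight-distribution dynamics
  the protocols measure. The same normalisation makes $g_0$ the exact fixed
  point of the rule under unstructured firing (see below).
* **Pairing.** All-to-all, event-driven: each neuron keeps presynaptic and
  postsynaptic exponential traces (decay $\gamma_+$, $\gamma_-$); a
  postsynaptic spike potentiates each incoming plastic synapse in proportion
  to the presynaptic trace, a presynaptic spike depresses it in proportion
  to the postsynaptic trace, and weights are clipped sequentially per event.
  Coincident ($\Delta T = 0$) spikes contribute nothing, enforced by a
  two-pass update within a time step. The trace formulation is verified
  against brute-force summation over all spike pairs to $10^{-9}$, and the
  compiled engine's weight path is verified against an independent R replay
  of the recorded spike trains.
* **Fixed point.** With these parameters the potentiation and depression
  rates balance at $g^\ast = A_+\gamma_+ / (A_+\gamma_+/g_{max} +
  A_-\gamma_-/g_0) = g_0$ for any *symmetric* distribution of spike-timing
  differences. Baseline weights are therefore a stable operating point of
  asynchronous activity, and directional change requires an *asymmetry* in
  spike timing — which is exactly what timescale mismatch under entrainment
  produces.

### Predicting the direction of change

The mean weight change per pairing can be predicted by integrating the STDP
window against the measured spike-timing-difference density $f(\Delta T)$
(`predicted_mean_change()`). Two variants are provided. The bare form
weights the branches by $A_+$ and $A_-$ alone; because $A_+ = 2A_-$ it is
strictly positive even for a flat $f$, so its sign conflates the rule's
built-in asymmetry with the timing structure. Supplying an evaluation
weight (`g = g_0`) applies the soft-bound factors, which balance exactly at
baseline: a flat distribution then predicts zero, and the sign tracks the
asymmetry of $f(\Delta T)$ alone. The sweeps and the acceptance checks use
the baseline-evaluated form; it agrees in sign with simulated weight changes
wherever both are statistically distinguishable from zero, which is the
package's independent cross-check of the simulator.

$f(\Delta T)$ is accumulated over all cross pairs within a $\pm 100$ ms
window (ten STDP decay constants, so the truncated tail of the integrand is
negligible) in 1 ms bins; both settings are configurable.

## Synthetic inputs

Every stochastic input is generated from an explicit, seeded distribution;
there are no external data dependencies.

* **Membrane time constants.** Gaussian with mean 10 ms and sd 3 ms for the
  single-layer study, truncated *by resampling* (not clipping, which would
  pile mass at the bound) to stay positive; sd = 0 gives the homogeneous
  control. Layer-resolved profiles for the laminar network are lognormal
  stand-ins — III: 8 ± 3, IV: 10 ± 3, V: 15 ± 5, VI: 20 ± 6 ms — chosen as
  *calibration defaults* that preserve only the empirically supported
  ordering (superficial layers faster than deep ones) and the positivity and
  right-skew of measured timescale distributions. They are not measured
  values, and every layer's family, mean, sd and bound can be overridden.
* **Rheobase calibration.** Because excitability falls steeply with
  $\tau_m$, slow layers would otherwise be nearly silent. Each layer
  receives a constant current offset calibrated by bisection so that
  isolated neurons drawn from its MTC distribution fire at the ~5 Hz sham
  operating point; offsets can also be supplied directly.
* **Weights, delays, noise.** Initial weights are Gaussian around the
  type-pair baseline with sd $0.1\,g_0$, clipped into the hard bounds;
  delays uniform in [0.5, 1] ms; the noise stream follows the
  Euler–Maruyama convention above. All generators are pure functions of
  (specification, seed); multi-trial protocols derive per-trial child seeds
  deterministically from one master seed and record them.

What the generator *does not* emulate: measured layer-specific MTC
densities (only their ordering), distance- or motif-structured connectivity
(wiring is Bernoulli-random), cell-type-specific timescale differences
(excitatory and inhibitory cells share one distribution), and any
field-to-membrane coupling physics. Passing tests therefore support the
mechanism — timescale mismatch plus entrainment steers plasticity — not a
quantitative prediction for any particular cortical area.

## Networks and protocols

Three builders cover the study designs: `build_pair_motif()` (two mutually
coupled excitatory cells, current-based plastic synapses),
`build_cortical_layer()` (balanced 4:1 E:I population, every ordered type
pair wired at probability 0.1), and `build_multilayer()` (four layers with
their own MTC profiles, intra-laminar wiring as above, inter-laminar E→E
projections at probability 0.05 where a configurable adjacency allows —
default: all ordered layer pairs — and no inter-laminar inhibition). The
full study scale is 10 000 neurons for the single layer and 12 000 for the
laminar network; the desk-scale defaults (2 000, and 600 per layer)
preserve all ratios and probabilities while keeping every protocol runnable
in minutes on one CPU. The test suite and acceptance script run at desk
scale; the full scale sits behind the builders' size arguments.

`run_protocol()` executes the epoched experiment — 4 s baseline,
stimulation until 40 s, recovery until 60 s by default — with plasticity
active throughout, snapshotting weights every 0.5 s and recording mean
synaptic drive per timescale-and-type group. Group summaries follow the
study's readout: synapses from mid-timescale presynaptic cells
($\tau_m \in [9.5, 10.5]$ ms) onto fast ($\tau_m \le 8$ ms) or slow
($\tau_m \ge 12$ ms) postsynaptic cells, averaged over the 0.5 s snapshots
in the last 5 s of stimulation; cells between the group thresholds simulate
but are excluded from summaries. `sweep_pair()` and `sweep_interlaminar()`
run the frequency × timescale and frequency × layer-pair sweeps; the
laminar readout sums weight changes over excitatory synapses whose MTC gap
is at least 5 ms, per ordered layer pair, comparing the end of stimulation
with the initial state.

## Numerical choices and degenerate inputs

$dt = 0.1$ ms throughout (halving it is a supported convergence check);
axonal delays are rounded to whole steps with a one-step minimum; the
delay ring buffer and the exponential kernel accumulators make synaptic
evaluation exact rather than window-truncated. Spike threshold uses
$v \ge v_{thr}$ on the post-update potential. Ties at $\Delta T = 0$
contribute no weight change. The engine draws its normals from a
self-contained Box–Muller generator over a 64-bit PRNG, so identical seeds
give bit-identical spike records across platforms and compilers; a
zero-length stimulation window is bit-identical to a sham run with the same
seed. Non-finite membrane values abort with a diagnostic rather than
propagating. Histograms handle empty inputs (zero mass), and circular means
are flagged undefined below a vector-strength floor.

## Known limitations

* The high-amplitude regime ($A_s = 1$ mV effective at the soma) is chosen
  to make entrainment — and therefore STDP recruitment — strong; firing
  rates rise during stimulation, which is not consistently observed
  experimentally. The low-amplitude protocol ($A_s = 0.2$ mV) shows the
  same directional weight effects at much smaller magnitude, but in this
  model even weak stimulation slightly elevates the population mean rate,
  because the convex rate–timescale profile rectifies the sinusoid most
  strongly in the fastest cells.
* Weight changes decay after stimulation offset; the rule has no
  consolidation mechanism, so the model makes no claim about persistence.
* The network operates in a weak-coupling regime: recurrent drive is small
  against the background input, which keeps the asynchronous irregular
  state stable but means population-level interactions contribute little to
  the single-cell entrainment that drives the effects.
* Results are reported conditional on the laminar adjacency used; the
  default all-pairs adjacency is a configuration choice, not anatomy.
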