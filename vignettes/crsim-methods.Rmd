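---
title: "Coordinated Reset stimulation in a plastic Hodgkin-Huxley network: model and methods"
author: "crsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated Reset stimulation in a plastic Hodgkin-Huxley network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crsim)
```

## The scientific problem

Several brain disorders are associated with abnormally strong neuronal
synchrony maintained by abnormally strong synaptic connectivity.  When
synapses are plastic, the two sustain each other: synchronized firing keeps
spike-timing-dependent plasticity (STDP) potentiating the very connections
that generate the synchrony.  Coordinated Reset (CR) stimulation tries to
break this loop by resetting sub-populations at staggered times, reducing
coincident firing so that STDP *unlearns* the pathological connectivity
("anti-kindling").  The decisive question for therapy design is how the
outcome — during stimulation, shortly after, and long after — depends on
the stimulation frequency and intensity.  `crsim` implements the in-silico
experiment used to map that dependence: a plastic spiking network, a
configurable CR stimulus, macroscopic outcome measures, and a sweep layer
with the accompanying statistics.

## The model

**Membrane dynamics.** Each of the $N = 200$ neurons follows standard
Hodgkin–Huxley dynamics,

$$C \dot V_i = I_i - g_{Na} m_i^3 h_i (V_i - V_{Na})
  - g_K n_i^4 (V_i - V_K) - g_l (V_i - V_l) + S_i + F_i,$$

with the usual voltage-dependent gating rates for $m$, $h$, $n$
(`hh_rates()`); the removable singularities of $\alpha_m$ at $-40$ mV and
$\alpha_n$ at $-55$ mV are replaced by their analytic limits within
$10^{-7}$ mV.  The constant drive $I_i$ is drawn uniformly from
$[I_0 - \sigma_I,\, I_0 + \sigma_I] = [10.55, 11.45]$ µA/cm², so neurons
are non-identical with intrinsic rates near 71 Hz.

**Synapses.** A presynaptic spike drives the neuron's postsynaptic
variable $s_j \in [0,1]$ through
$\dot s_j = 0.5\,(1 - s_j)\,\sigma(V_j) - 2 s_j$ (`psp_derivative()`), and
the input to neuron $i$ is the population average

$$S_i = N^{-1} \sum_j (V_{r,j} - V_i)\, c_{ij}\, |M_{ij}|\, s_j ,$$

where the spatial profile on the ring is a Mexican hat,
$M_{ij} = (1 - d_{ij}^2/\sigma_1^2)\exp(-d_{ij}^2/(2\sigma_2^2))$, with
ring distance $d_{ij} = d\min(|i-j|, N - |i-j|)$ and lattice spacing
$d = d_0/(N-1)$.  Connections with $M_{ij} > 0$ (ring distance below
$\sigma_1 = 3.5$, i.e. up to 69 steps at the default geometry) are
excitatory with reversal potential $+20$ mV; longer-range connections are
inhibitory with $-40$ mV.  The class of each connection is fixed; only its
weight $c_{ij} \in [0,1]$ evolves.  There are no self-connections.

**Plasticity.** Every spike of a postsynaptic neuron $i$ updates its
connections by $\pm\delta\,\Delta c(\Delta t)$, with
$\Delta t = t_i - t_j$ the post-minus-pre lag and the asymmetric kernel

$$\Delta c(\Delta t) =
 \begin{cases}
 \beta_1\, e^{-\Delta t/(\gamma_1 \tau)}, & \Delta t \ge 0,\\[2pt]
 \beta_2\, \frac{\Delta t}{\tau}\, e^{\Delta t/(\gamma_2 \tau)}, & \Delta t < 0,
 \end{cases}$$

($\beta_1 = 1$, $\beta_2 = 16$, $\gamma_1 = 0.12$, $\gamma_2 = 0.15$,
$\tau = 14$ ms, $\delta = 0.002$).  The increment is *added* on excitatory
and *subtracted* on inhibitory connections — the literal reading of the
rule this model family uses — so coincident firing strengthens excitation
and weakens inhibition.  Weights are clipped to $[0, 1]$.  Near-coincident
spikes potentiate; lags beyond roughly a millisecond depress strongly
($|\Delta c(-2\,\text{ms})| \approx 0.88$ versus
$\Delta c(+2\,\text{ms}) \approx 0.30$), which is what allows
desynchronized firing to unlearn strong coupling.

**Pairing scheme.** The rule fires "every time a neuron spikes" and we pair
each spike with the partner's *most recent* spike only (nearest-spike
pairing), in both directions.  This keeps the plasticity state bounded
(one last-spike time per neuron) and makes the event stream exactly
replayable; `stdp_oracle()` is an independent brute-force replay used by
the tests.  Simultaneous spikes ($\Delta t = 0$) take the potentiation
branch, and within an integration step spikes are processed in ascending
order of their interpolated times (ties by index).

**CR stimulation.** Four sites sit at neurons 25/75/125/175.  Within an ON
cycle of length $T_s$ each site is activated exactly once for
$T_s/N_s$; the activation order (the *sequence*) is a random permutation,
drawn fresh every cycle (RVS) or held for $l$ cycles before switching
(SVS-$l$).  ON cycles come in blocks of $m = 3$ followed by $n = 2$ silent
cycles.  An activation at onset $t_k$ evokes the α-conductance
$G(t) = \frac{t - t_k}{\tau_{stim}} e^{-(t-t_k)/\tau_{stim}}$ with
time-to-peak $\tau_{stim} = T_s/(6 N_s)$, valid until the next activation,
spatially weighted by the quadratic decay
$D(i, x_k) = 1/(1 + d^2 (i - x_k)^2/\sigma_d^2)$, $\sigma_d = 0.8$.  The
total stimulation current is
$F_i = (V_r - V_i) K \sum_k D(i, x_k)\rho_k(t) G(t)$ with $V_r = 20$ mV
and intensity $K$.  Slot windows are half-open, so exactly one indicator
$\rho_k$ is 1 at any ON instant; onsets sit deterministically on the slot
grid, the randomness lives entirely in the sequences.

**Outcome measures.** Connectivity is summarized by the sign-weighted mean
weight $C_{av} = N^{-2}\sum_{ij}\mathrm{sgn}(M_{ij}) c_{ij}$; synchrony by
the Kuramoto order parameter $R(t) = |N^{-1}\sum_j e^{i\varphi_j(t)}|$
computed from linearly interpolated spike phases.  Endpoints report
$R_{av}$, the mean of $R$ over the last $100\,T_s$ of an epoch; plotted
series use a centered moving average over $400\,T_s$.  Neurons without a
bracketing spike pair at a sample time have no defined phase and are
excluded from that sample's phasor mean (the exclusion count is recorded);
an alternative would be to freeze their last phase, but excluding is the
cleaner reading of a phase that is simply undefined.

## The experiment

`run_protocol()` executes the four phases in one continuous trajectory:

1. **equilibration** (2 s): no plasticity, no stimulation — the random
   initial conditions relax onto the firing regime;
2. **kindling** (60 s): STDP alone rewires the network into a strongly
   coupled, synchronized state firing near the intrinsic ~71 Hz rate (the
   suite asserts the rate within +/-3 Hz and an endpoint order parameter
   above 0.6);
3. **CR-on** (128 s): STDP plus CR stimulation with the chosen
   $(K, T_s, \text{mode})$;
4. **CR-off** (128 s): stimulation ceases, STDP continues — this phase
   separates acute effects from the long-lasting anti-kindling.

`run_sweep()` runs grids over $(K, T_s)$ and protocol mode across
replicate networks.  Each replicate network is kindled once and the
kindled snapshot is reused for every cell — the same set of networks is
stimulated across the whole grid, and the 62 s pre-stimulation history is
not recomputed per cell.  The seed table is `seed + network_id` for
initial conditions and a cell-specific derived seed for the sequence
stream, so any record can be reproduced in isolation.

## The synthetic-data generator

All data are generated by the simulator itself; the "generator" is
`init_network()` plus the stream constructors.  Its defaults *are* the
study conditions: uniform membrane/gating initial conditions, uniform
drive currents on $[10.55, 11.45]$ µA/cm², weights
$\mathcal N(0.5, 0.01)$ clipped to $[0,1]$, 200 neurons, the Mexican-hat
geometry above.  What it emulates is an idealized cortical-like patch with
distance-dependent connectivity and heterogeneous excitability.  What it
does **not** emulate: conduction delays, synaptic noise and channel
stochasticity, non-ring topologies, heterogeneous neuron models, or
closed-loop stimulation.  Tests passing on this generator therefore show
that the *mechanism* (CR-induced unlearning under STDP) is implemented
faithfully, not that the parameter maps transfer quantitatively to real
tissue.

## Numerical choices

* **Integrator:** fixed-step classical RK4 at `dt = 0.05` ms.  The source
  model description does not state an integrator; RK4 at 0.05 ms resolves
  the ~1 ms spike upstroke, and the test suite checks convergence by step
  halving (the mean weight at fixed time moves by less than $10^{-3}$) and
  agreement of an uncoupled neuron with a tight-tolerance `deSolve::lsoda`
  reference to within 0.5 mV over 100 ms.
* **Settling window:** uniformly random gating variables put the first
  milliseconds of a run far off the nullclines, where derivatives
  transiently reach $10^4$ mV/ms and a 0.05 ms step is unstable.  The
  first 20 ms of any run started from a raw state (no spike history) are
  therefore integrated at 0.001 ms before the production step takes over.
* **Spike detection:** strict upward crossing of 0 mV with linear
  interpolation of the crossing time inside the step and a 2 ms
  refractory guard; a sample sitting exactly on the threshold is not a
  crossing.  Weight updates are applied after the step in which the spike
  was detected; weights are piecewise constant within a step.
* **Stability guard:** the integrator aborts with a diagnostic if any
  $|V_i|$ exceeds 200 mV (HH trajectories peak near +40 mV, so this only
  triggers on genuine blow-up).
* **Fast paths:** all gating exponentials share the base
  $e^{-(V+65)/720}$ — every rate exponent is an integer power of it times
  a constant — evaluated by a degree-10 Taylor polynomial (relative error
  $< 2\times10^{-11}$ on the guarded voltage range).  The effective
  coupling $c_{ij}|M_{ij}|$ is cached transposed in single precision for
  the inner products of $S_i$; the weight matrix itself is double
  precision and authoritative, and the cache is patched in place at every
  weight update.  These choices change trajectories only at the float
  rounding level, far below the seed-to-seed variability the experiment
  averages over.
* **Quartile convention:** `boxplot_stats()` interpolates linearly between
  order statistics (the default type-7 convention), and the fences are
  $Q_1 - 1.5\,\mathrm{IQR}$ and $Q_3 + 1.5\,\mathrm{IQR}$.  The source
  material does not state its convention; this one is declared and used
  consistently, and it only affects outlier labelling.
* **Degenerate inputs:** empty schedules return the initial snapshots;
  epochs shorter than $100\,T_s$ report `NA` for $R_{av}$ rather than a
  window average they cannot support; silent neurons are excluded from
  $R$ samplewise as described above.

## Design choices where the design was open

* **Ring metric everywhere.**  The distance clause in the model
  description attaches the wrap-around rule to an ambiguous condition; we
  apply $d\min(|i-j|, N-|i-j|)$ to *all* pairs.  Anything else would break
  the symmetry the ring exists to provide ("to limit boundary effects"),
  and the profile would not be translation invariant.
* **STDP exponent normalization.**  The kernel exponents are read as
  $\Delta t/(\gamma\tau)$ (division), following the explicit remark that
  the ratio is normalized; the typography would also admit
  multiplication, which would make the potentiation window ~1.7 µs and
  plasticity inert.
* **Inhibitory update sign.**  "Add or subtract ... for excitatory or
  inhibitory connections respectively" is implemented literally: the same
  kernel value is subtracted on inhibitory connections, so coincidence
  weakens and anti-coincidence strengthens inhibition.
* **Sequence consumption.**  The ON-cycle ordinal, not wall-clock time,
  indexes the sequence stream: OFF cycles do not consume sequences.  A
  trailing partial ON block at the end of the CR-on epoch is truncated at
  the epoch boundary.
* **`duration_scale` semantics.**  In sweeps it scales only the CR-on and
  CR-off epochs.  Equilibration and kindling keep their full lengths, so
  scaled-down stimulation is always probed against the same kindled
  baseline as the full experiment.
* **Table conversions.**  The frequency-ratio table is generated from the
  integer periods; because periods are rounded to whole milliseconds the
  forward map does not always return the design ratio (e.g. 85% → 19 ms
  → 84%).  `period_for_ratio()` implements the design direction,
  `ratio_for_period()` the reporting direction, and the tests pin both.

## Problem sizes used by the test suite

The full study grid (11 networks × ~77 cells × 256 s each) is
cluster-scale by design and ships as a configuration
(`sweep_spec()` defaults), not as a test.  The package's own experiments
use: the complete 2 s + 60 s kindling phase at $N = 200$ for the firing
rate and kindled baseline (three replicate networks); a scaled-down
anti-kindling contrast (three networks, CR-on/off 32 s each, $K = 0.20$,
$T_s \in \{10, 64\}$ ms, RVS) that reproduces the qualitative structure of
the full maps — strong sustained anti-kindling near the intrinsic period,
none at the lowest frequency; and 20-neuron fixtures for integrator,
plasticity and protocol property tests.  These sizes are the package's
choice of a desk-scale replication; medians over three networks are
noisier than over eleven, which is why the contrast checks use wide
qualitative margins rather than printed map values.

## Known limitations

* Nearest-spike pairing is the only implemented STDP pairing scheme.
* The phase-entrainment statistic of the stimulated sub-populations (an
  supplementary-level analysis in the source study) is not implemented;
  sub-population order parameters are.
* No conduction delays, noise terms, or non-ring topologies.
* State containers are RDS + CSV rather than HDF5; the on-disk layout is
  a plain named list and documented in `save_network_state()`.
* `R(t)` is sampled on the recording grid (default every 1 ms), not every
  integration step; endpoint averages over $100\,T_s$ are insensitive to
  this at the default stride.
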