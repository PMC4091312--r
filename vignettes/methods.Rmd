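---
title: "Models, cost functions and numerical choices in neurofitr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, cost functions and numerical choices in neurofitr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofitr)
```

`neurofitr` fits the parameters of neuronal models by minimizing a weighted
combination of normalized trace-comparison cost functions with
bound-constrained optimizers. This vignette is the package's account of the
science behind it: the models, the error measures, the numerical choices,
and what the shipped validation does and does not establish.

## The fitting problem

A fit is specified by five ingredients: the target data (one or more
uniformly sampled voltage or current traces), the model backend and its
fixed settings, the tunable parameters with mandatory finite bounds, the
stimulation/recording protocol, and the cost specification. All internal
units are mV, nA and ms. Before anything else the target is aligned with
the model grid: if the data are sampled faster than the model step, the
simulation step is reduced to the data step; if slower, the data are
linearly interpolated onto the model grid, and the re-sampled set *is* the
target from then on. Every cost function then assumes (and asserts) equal
sampling step and length, so misaligned inputs are an error rather than a
silent re-sampling.

## Cost functions

All eleven features are normalized so that their values are at least
approximately in $[0,1]$, which makes the user-supplied weights meaningful
as relative importances. With $s$ the simulated and $x$ the target trace of
$n$ samples, duration $T$, and $R = \max x - \min x$:

* **mse** $= \frac{1}{n R^2}\sum_i (s_i - x_i)^2$.
* **mse_excl_spikes**: the same mean restricted to samples farther than a
  half-width $h$ (default 5 ms) from every spike peak detected in *either*
  trace; the normalization range stays that of the full target. With no
  spikes anywhere it equals `mse` exactly.
* **deriv_diff**: `mse` applied to central-difference temporal derivatives
  (one-sided at the ends), normalized by the squared target-derivative
  range. The normalizing constant is the package's choice, mirroring the
  `mse` convention.
* **spike_count** $= |n_s - n_x| / (n_s + n_x + 1)$; the $+1$ makes two
  spikeless traces score 0 instead of 0/0.
* **spike_count_stim**: the same restricted to peaks inside the stimulus
  window.
* **isi_diff**: sum of $|\Delta \mathrm{ISI}_k|$ over the first
  $\min(n_s, n_x) - 1$ inter-spike intervals (spikes paired in order,
  extras ignored), divided by $T$.
* **latency** $= (t_{s,1} - t_{x,1})^2 / T^2$; a spikeless trace
  contributes latency $T$, and the value is capped at 1, so the penalty
  stays finite and smooth for the optimizer.
* **ap_overshoot**: mean squared difference of action-potential amplitudes
  over ordered pairs, normalized by the squared maximal target amplitude.
  Amplitude is peak voltage minus threshold voltage.
* **ap_width**: mean squared difference of half-amplitude widths,
  normalized by the squared mean target width. Width is measured at
  threshold + amplitude/2 with linear interpolation at the two crossings.
* **ahp_depth**: the *square of the mean* difference in
  after-hyperpolarization depth (the literal reading of "squared average of
  the differences"), normalized by the squared sub-threshold range of the
  target (its range after removing the spike exclusion windows). The
  alternative mean-of-squares reading is available as
  `cost_spec(..., ahp_mode = "mean_squared")`.
* **pptd**: both traces are mapped to phase-plane clouds $(V_i, \dot V_i)$,
  binned on a shared $G \times G$ grid ($G = 64$ by default) spanning the
  joint bounding box, and compared by total-variation distance
  $\tfrac12\sum_b |p_b - q_b|$ — bounded by 1, symmetric, zero only for
  identical histograms.

Spikes are maximal contiguous supra-threshold excursions of the voltage
(default detection threshold 0 mV, which separates full action potentials
from sub-threshold activity in all built-in use cases). The
action-potential threshold voltage entering amplitude is *defined* as the
detection threshold: the tool exposes no dV/dt criterion, so this keeps the
features reproducible and parameter-free. The AHP search window runs from
each spike's offset to the next spike's onset (the last spike searches to
the stimulus end or trace end). Mismatched spike counts truncate paired
features to the first $K$ pairs; $K = 0$ with differing counts returns the
maximal value 1 so the objective stays finite.

When target and simulation contain several traces, each feature is summed
over the corresponding pairs, and the total is the weighted sum of those
accumulated values (weights rescaled to sum to 1 unless normalization is
switched off).

## Simulation backends

**Hodgkin–Huxley step response** (`hh_step`). A cylindrical single
compartment (membrane area $\pi \cdot \mathrm{diam} \cdot L$) carrying the
classical squid-axon Na$^+$, K$^+$ and leak conductances at 6.3 °C
(reversals 50, −77, −54.3 mV, $C_m = 1\,\mu\mathrm{F/cm^2}$), with the
three densities as the tunable parameters. The numerics deliberately follow
the default pipeline of the standard compartmental simulator: a staggered
scheme alternating an implicit (backward-Euler) voltage step with frozen
conductances and analytic exponential updates of the gating variables, with
gating steady states and time constants read from a 201-point rate table on
[−100, 100] mV by linear interpolation. This choice is load-bearing. At the
200 pA step of the first use case the firing rate sits just at the margin
between 27 and 28 spikes per 500 ms: a high-accuracy continuous solution
of the exact rate functions (adaptive multistep at rtol 10⁻¹⁰, or the
staggered scheme with exact rates at any step size) produces 27 spikes,
whereas the tabulated rates — i.e. what reference simulations of this
model actually evaluate — shorten the inter-spike interval by ~0.5 % and
produce the expected 28. The
spike count is stable under dt halving (28 at dt 0.025, 0.0125, 0.00625 and
0.002 ms); the onset of firing is grid-converged, while the phase of late
spikes drifts by up to ~1.7 ms between dt 0.025 and 0.0125 because period
errors accumulate along a marginal ~56 Hz cycle. Sub-threshold, the scheme
agrees with an independent high-accuracy ODE solution to better than
0.05 mV (tested against `deSolve`).

**Voltage-clamped synapse** (`synaptic_vc`). The same compartment held
ideally (zero series resistance) at a holding potential; the recorded trace
is the clamp current in nA, outward positive: the constant steady-state
ionic current at the holding voltage plus
$g(t)\,(V_{\mathrm{hold}} - 0)$ for a double-exponential conductance
$g(t) = w N (e^{-t/\tau_2} - e^{-t/\tau_1})$, peak-normalized so
$\max g = w$, reversal 0 mV (excitatory), one term per input spike after
the synaptic delay. This is closed-form, so the backend is exact on the
grid. A rise time at or above the decay time is clamped to
$0.9999\,\tau_2$, mirroring the standard two-exponential synapse
implementation — necessary because optimization bounds for rise and decay
overlap, and candidate vectors with $\tau_1 \ge \tau_2$ must still be
simulable.

**Adaptive exponential integrate-and-fire** (`adexp`). The two-variable
system $C\dot V = -g_L(V - E_L) + g_L \Delta_T e^{(V-V_T)/\Delta_T} - w +
I$, $\tau_w \dot w = a(V - E_L) - w$, integrated with fixed-step RK4; the
exponential argument is capped at $(V_{\mathrm{cut}} - V_T)/\Delta_T$ with
$V_{\mathrm{cut}} = V_T + 5\Delta_T$ for numerical safety. When $V$ reaches
$V_{\mathrm{cut}}$ the crossing is located by linear interpolation within
the step, the spike is drawn as a single sample at $V_{\mathrm{cut}}$ (so
threshold-based detection finds it), $V$ is reset and clamped for the
refractory period (quantized to the sample grid), and $w$ jumps by $b$
while continuing to relax during the clamp.

**External black boxes** (`external`). Any simulator that accepts parameter
values appended to its command line (full decimal precision, declared
order) and writes the resulting trace set as a plain-text file on the
protocol grid can be fitted. Nonzero exit status, missing output and
malformed output are distinct, attributed errors. The file dialect —
whitespace-separated columns, one per trace, no header, no time column — is
the package's own defined contract; time is implied by the declared
sampling step.

## Optimizers

All algorithms work on parameters normalized to $[0,1]^d$ and the
re-normalized (physical) values are passed to the simulator; candidates are
clipped to the cube, and the test suite asserts that no objective
evaluation ever escapes it.

The **evolutionary algorithm** uses uniform random initialization (a
user-supplied start replaces one member), tournament selection, blend
crossover (per-gene uniform sampling on the parents' interval extended by
$\alpha = 0.1$), per-gene Gaussian mutation with probability 0.25, and
generational replacement with weak elitism (the best individual always
survives), population 100 by default. Two operator parameters were left
open — no canonical values exist for them — and are set by this package's
own measurements on the shipped surrogate tasks: the tournament size defaults
to 8, and the mutation scale anneals geometrically from 0.2 to $10^{-5}$
(normalized units) across the generation budget. With binary tournaments
and a fixed scale the population never condenses enough to refine the
optimum (the synaptic task stalls around a normalized error of $10^{-4}$);
with the defaults, 4 of 5 seeds at population 100 × 100 generations recover
all four synaptic parameters to better than 0.02 %, and the fifth lands in
a visibly worse local basin. Roughly $10^4$ evaluations are needed on that
task — at population 50 × 40 generations no tested operator variant
recovers the parameters, which is why the shipped recovery test runs the
full budget.

**Simulated annealing** is the canonical single-state Metropolis scheme
with geometric cooling ($T \leftarrow c\,T$ every `dwell` evaluations from
$T_0$ to $T_f$, within a `generations × dwell` evaluation budget). The
Gaussian proposal scale is multiplied by $\sqrt{T/T_0}$ so the cold phase
refines rather than re-samples; one configurable implementation with a
free schedule covers both common variants of the method.
**Nelder–Mead** and **L-BFGS-B** are the `stats::optim` implementations
(bounds by clipping for the simplex, native box constraints and
finite-difference gradients for the quasi-Newton method), started from the
user's point or the cube center. Every path records per-generation
best/mean/median/worst statistics, the final population, and the exact
evaluation count; identical settings and seed give bit-identical results
because all randomness flows from one seeded generator.

## Surrogate data: what it shows and what it does not

The generator produces the three validation conditions at their reference
values: the 1000 ms, 28-spike HH step response (200 pA, 200–700 ms,
dt 0.025 ms, $V_0 = -65$ mV); the clamp current at −70 mV of the
double-exponential synapse (rise 0.3 ms, decay 3 ms, peak 0.01 µS, delay
2 ms) driven by four spikes 100 ms apart; and a four-amplitude (0.30–0.45
nA, 1100 ms, 5 kHz) integrate-and-fire set. The third case's generating
parameters are a synthetic, physiologically plausible pyramidal-cell set
(C 0.2 nF, g$_L$ 0.012 µS, rheobase just below 0.30 nA so the amplitudes
span ~10–30 Hz) — no reference parameter set exists for this
case, so it exercises the multi-trace machinery rather than
reproducing that figure. Optional additive Gaussian noise on the recorded
variable emulates recording noise; it is i.i.d. and white, which real
electrode noise is not, and the generator shares the simulation backends
with the fitting path, so recovery tests validate the optimization
machinery, not the backends' fidelity to any real neuron.

One honest negative result belongs here. For the HH use case, the plain
point-by-point mean squared error between the best-fit and target traces is
*not* a quantity this tool (or, we believe, any stochastic search at this
budget) can drive to the reference order of magnitude (~0.003 mV²): on a marginal limit
cycle a 0.05 % change of one conductance already shifts late spikes enough
to cost tens of mV², so the set of parameter vectors matching the full
trace to ~0.003 mV² is a needle of relative width ~10⁻⁴ around the exact
generating values. The prescribed cost (sub-threshold error + spike count)
is nearly flat across a valley of spike-count-correct,
sub-threshold-equivalent solutions — every seed finds the correct 28
spikes, repeated seeds give near-equal costs at materially different
conductances (the known non-identifiability of these conductance densities under a
single step stimulus), but the
full-trace error of those solutions remains orders of magnitude above the
needle. The acceptance suite therefore reports the raw MSE as computed and
one criterion stays red by design rather than being weakened.

## Numerical and design choices, in one place

* Canonical units mV/nA/ms; trace files carry no time column.
* Spike detection threshold 0 mV by default; exclusion half-width 5 ms;
  both settable per cost specification.
* Degenerate cases are defined, not exceptional: two spikeless traces cost
  0 on every spike feature; $K=0$ with differing counts costs 1; a
  constant trace pair has `pptd` 0; an all-excluded sub-threshold error is
  an error (the objective would be undefined).
* Out-of-bounds optimizer candidates are clipped, not rejected.
* XML configurations are strict: unknown tags, missing tags and invalid
  enum values fail at load time with the offending tag named — a deliberate design choice
  favouring early, attributable failures.
* Problem sizes in the shipped tests (population 100, 50–100 generations,
  three to five seeds) are the package's validation choices: large enough
  that the synaptic task recovers its parameters to the reference precision
  and the HH task reproduces the reference spike count and
  non-identifiability, small enough to run on one CPU in minutes.

## Known limitations

Single-objective only; one data type per fit (no mixed voltage + spike-time
targets); built-in models are single-compartment (multi-compartment models
are reachable only through the external contract); no variable-time-step
integration; the black-box file contract is this package's own definition. The AHP-depth wording ambiguity
is resolved by a documented switch rather than a guess.
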