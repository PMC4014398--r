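---
title: "Channel noise, travelling action potentials and synaptic variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel noise, travelling action potentials and synaptic variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

stochaxon simulates action potentials (APs) propagating along thin
unmyelinated axons in which every voltage-gated channel is an individual
Markov chain, quantifies the waveform variability that channel gating noise
imposes on the travelling AP, and propagates the arriving waveforms through
a presynaptic Ca++/vesicle-release cascade. This vignette is the package's
account of the underlying models, the numerical machinery, and the design
choices that were genuinely open.

## The biophysical model

### Markov channel populations and the binomial algorithm

Each channel type is a `kinetic_scheme`: a finite-state Markov chain with
voltage-dependent transition rates (1/ms) and a set of conducting states
carrying the single-channel conductance. The built-in squid schemes expand
the classical gate description into an 8-state Na+ lattice (three
activation subunits and one inactivation subunit; conducting state `m3h1`)
and a 5-state K+ chain (`n0`..`n4`, conducting `n4`), with rates multiplied
by subunit multiplicities (3 alpha_m out of `m0`, etc.).

A population of N channels per compartment is advanced with the binomial
algorithm: over a step dt, the number of channels taking a transition with
rate r is drawn as Binomial(n_available, r dt). For states with several
exits the exits are sampled sequentially, in declared order, each from the
occupancy remaining after the previous draws, so channel counts are
conserved exactly as an integer identity. The deterministic mode replaces
each draw by its expectation (same sequential depletion), which makes the
deterministic run the exact ensemble mean of the stochastic update and
bit-reproducible: any ensemble spread in deterministic mode is exactly
zero, so channel noise is the only noise source in the stochastic runs.

At stationarity under voltage clamp the open-channel count is binomial:
mean N p and variance N p (1 - p), where p is the conducting-state mass of
the chain's stationary distribution (`equilibrium_distribution()`). The
test suite verifies both against the compiled sampler.

### The cable

The axon is a cylinder of diameter d discretized into compartments of
length dx with sealed (zero axial flux) ends. Membrane capacitance,
leak, axial coupling pi d^2 / (4 R_a dx) and channel counts
round(density x pi d dx) follow from the geometry. Compartment length is
held to dx <= lambda/10, with lambda = sqrt(R_m d / (4 R_a)) the passive
length constant. The voltage update is an implicit theta-scheme
(Crank-Nicolson by default) solved with the Thomas tridiagonal algorithm,
unconditionally stable at fine spatial grids; channel states advance at the
same dt by operator splitting, evaluated at the updated potential.

### Interneuron kinetics and the m-gate temperature factor

The rat-interneuron preset uses the canonical fast-spiking interneuron
rate functions with the published temperature factor phi = 5 on the h and
n gates. The source model treats Na+ activation (m) as instantaneous,
which a Markov population cannot represent. Using the published m rates
unscaled makes activation as slow as the accelerated inactivation; the
model then cannot produce an overshooting AP, and with the spike-train
passive parameters it settles into a stable depolarized Na+ window-current
plateau near -34 mV (a genuine fixed point of the conductance balance,
verified analytically and by simulation). We therefore scale the m rates
by the same phi = 5: the steady-state curves are untouched and activation
remains much faster than inactivation, which is precisely what the
instantaneous-gate idealization encodes. This is the package's
finite-rate approximation of that idealization, and the one genuinely free
constant in the preset: the absolute excitability of the model (pulse
threshold, and hence the firing rate under a fixed noise stimulus) is
sensitive to it, as discussed under Limitations.

## Protocols (the synthetic-data generators)

All inputs are generated; there is no external data. Two protocols define
the study conditions:

* **Single spike per trial** (`run_single_ap_protocol()`): identical
  initial conditions and an identical trigger in every trial; only the RNG
  stream differs. The trigger amplitude is not part of the published
  protocol, so the package defines it reproducibly: a 0.5 ms rectangular
  pulse at the proximal end, auto-tuned by bisection on the deterministic
  model to 1.5x the threshold for exactly one propagating distal AP.
  Trials with 0 or >= 2 detected APs at any site are excluded and counted.
* **Spike train** (`run_spike_train_protocol()`): a zero-mean Gaussian
  current, low-pass filtered and rescaled so its realized SD is exactly
  0.01 nA, injected at the proximal end after a 20 ms settling period.
  "1 kHz corner frequency" fixes only the -3 dB point; the package uses a
  first-order low-pass, the simplest filter consistent with that
  specification, and records the choice in run metadata. Passive
  parameters follow the convention of the source tables: the preset leak
  (R_m = 10000 Ohm cm^2) for single-AP runs, and R_a = 70 Ohm cm with
  R_m = 20000 Ohm cm^2 for spike trains.

What the generators emulate: travelling APs whose only variability source
is channel gating noise, at the printed channel densities, conductances
and reversals. What they do not emulate: synaptic bombardment, other
channel types (e.g. A-type or persistent currents), inhomogeneous
geometry, myelination, temperature gradients, or stochastic Ca++ channels
at the terminal (the cascade's Ca++ channel is deterministic by design).
Tests passing under these conditions show the machinery is correct and
that channel noise alone reproduces the study-scale statistics; they do
not show that real axons contain no other noise sources.

## Waveform analysis

APs are detected with a threshold discriminator (default V_rest + 40 mV,
2 ms lockout) and aligned at the rising crossing of the half-height level,
found by linear interpolation between samples, so alignment and width have
sub-sample resolution. Height is reported as resting-to-peak (the absolute
peak potential is also carried in the event table); the half-height level
is V_rest + 0.5 (V_peak - V_rest). Width is the delay between rising and
falling crossings of that level. All spreads use the population SD
convention (divide by n); at the ensemble sizes used the difference from
the sample convention is negligible, but the convention is fixed for
reproducibility. The variability profile is the pointwise mean, SD and
3xSD envelope of aligned waveforms on a common grid; the scaling law is an
ordinary least-squares line in log-log coordinates of CV against diameter.

## The presynaptic cascade

The Ca++ channel is a deterministic conductance-based model with two
identical gating particles (open probability m^2) integrated along the
clamped arriving waveform with an exact exponential update per sample.
Its rate constants and reversal potential are not printed in the study
this package models; the defaults are the standard calyx-terminal
exponential rate functions (alpha = 1.78 e^{V/23.3}, beta = 0.14 e^{-V/15}
per ms, E_Ca = +45 mV), fully exposed in `ca_channel_model()`. The
current is scale-free: only its waveform matters downstream.

The local Ca++ transient preserves the current's rise time, lengthens its
half-width by 100 us (the post-peak segment is time-dilated, because the
rise is explicitly conserved), and is mapped affinely to a 50 nM resting
level and a 12 uM peak. For an ensemble the 12 uM scaling uses one common
factor (ensemble-mean peak -> 12 uM): scaling each AP individually would
erase the per-AP peak variation that the cascade is supposed to propagate.
A single transient scales exactly to 12 uM.

Vesicle release follows the allosteric five-site model: binding
n -> n+1 at (5-n) k_on [Ca], unbinding n -> n-1 at n k_off b^{n-1}, and
fusion from any state n at l+ f^n with f = 31.3 and
l+ = 2 x 10^-4 s^-1. k_on = 0.1 /uM/ms, k_off = 4 /ms and b = 0.5 follow
the source allosteric model; all are configurable, and l+ accepts an
override because parts of the literature quote per-ms rates. The
readily-releasable pool (default 2000) is a pure multiplicative constant:
every CV reported is pool-independent. The master equation is linear, so
occupancies plus the released fraction sum to one exactly; the integrator
(RK4 with automatic substepping for stiff high-Ca intervals) preserves
this to ~1e-12 and is cross-checked against an independent stiff ODE
solver in the tests.

## Numerical choices

* **Time step.** Default dt = 5 us. The per-state guard refuses a step if
  the summed escape probability exceeds 0.5; inside the compiled
  integrator, a compartment whose occupied states exceed 0.35 is locally
  substepped instead (fast deactivation rates at hyperpolarized
  potentials act on nearly empty states and would otherwise force a
  globally tiny dt). Halving dt changes deterministic AP width and height
  by well under 1% (tested).
* **Space step.** Default dx = 10 um, about lambda/20-lambda/40 for the
  axons studied; halving dx changes deterministic AP features by < 1%
  (tested).
* **Rates.** Transition rates are tabulated on a 0.01 mV grid over
  [-120, 100] mV and linearly interpolated in the compiled core; this
  agrees with direct evaluation to better than 1e-6 relative (tested).
* **Voltage scheme.** theta = 0.5 (Crank-Nicolson, second order). The
  charge-bookkeeping test uses theta = 1, where the discrete identity
  C dV/dt = I_stim - I_ion holds exactly against the recorded currents.
* **Degenerate inputs.** Blow-up (|V| > 200 mV) aborts with position and
  time; ill-conditioned stationary systems (reducible chains) are refused;
  suprathreshold excursions that never return below half-height are
  discarded with a warning; non-positive CVs are excluded from the
  power-law fit with a warning.
* **Problem sizes.** The package's desk-scale defaults are 2 mm axons,
  50-300 APs per ensemble, and 10-60 s spike trains, which reproduce the
  study-scale statistics with sampling errors of a few percent; the full
  published scale (1-2 cm, 10 min, N = 2000) is reachable by raising the
  same arguments.

## Limitations

* The interneuron model's absolute excitability depends on the
  finite-rate stand-in for the instantaneous m gate (see above). With
  phi = 5 on m, the model reproduces the study's AP shape and its width
  and height CVs well, but it is somewhat more excitable than the
  published model: the same 0.01 nA noise stimulus elicits roughly 70 Hz
  rather than ~41 Hz. A higher rate means more short interspike
  intervals, which inflates the height variability at the distal site
  (refractory interaction) and, through the cascade's height-sensitive
  Ca++ current, shifts the stage-level CVs relative to the published
  table. This is documented rather than re-tuned: lowering the m-gate
  factor to chase the published rate would abandon the instantaneous-gate
  idealization that defines the model.
* The cascade's stage-level statistics also depend on the unprinted calyx
  Ca++-channel rate constants; the printed transient parameters (12 uM,
  +100 us, 50 nM) are honoured exactly and are parameter-independent.
* Mid-to-distal feature correlations in spike trains are dominated by
  ISI-history common variation at the simulated firing rate, so they do
  not reproduce the near-zero published correlations; per-AP *differences*
  (the quantity the study quantifies) are reproduced.
* Propagation failures, myelination, branching and extracellular coupling
  are out of scope.
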