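---
title: "Methods: an E/I lattice model of EEG-like waves under synaptic depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an E/I lattice model of EEG-like waves under synaptic depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stdwaves` simulates a balanced cortical module — excitatory (E) and
inhibitory (I) integrate-and-fire neurons on a periodic lattice, coupled
through synapses that undergo short-term depression (STD) — and analyses the
EEG-like rhythms of its population activity.  This vignette is the package's
own account of the model, its parameters, the numerical choices behind the
implementation, and what the accompanying tests do and do not establish.

## The model

**Topology.**  E neurons occupy all `e_side^2` integer sites of a periodic
square lattice (default `e_side = 14`, so 196 E); I neurons occupy the
plaquette centers of a spacing-2 superlattice (49 I), giving the 4:1 E:I
count of a balanced cortical module.  Each I neuron inhibits the 12 E
neurons inside an inner circle around it and is excited by the 32 E neurons
inside an outer circle; there are no E–E or I–I connections.  The plaquette
placement is the unique simple geometry for which circular cutoffs produce
exactly those counts: squared distances from a plaquette center to E sites
come in shells 0.5 (4 sites), 2.5 (8), 4.5 (4), 6.5 (8), 8.5 (8), so a
strict cutoff at 4.5 selects 12 and an inclusive cutoff at 8.5 selects 32.
Note the inner cutoff must be *strict* — including the 4.5 shell would give
16 targets, not 12.  The construction is verified in the test suite against
brute-force distance enumeration for every I neuron.  `rewire()` adds
small-world randomness: each edge is independently re-pointed with
probability `pr` to a uniformly random E not already connected to that I,
preserving the 12/32 degrees exactly.

**Membrane dynamics.**  Each neuron is a leaky integrator,
$\tau(V)\,\dot V = -V + V_\mathrm{in} + V_\mathrm{noise}$, with asymmetric
relaxation: $\tau = \tau_1 = 16$ ms above the resting potential (0 mV) and
$\tau = \tau_2 = 26$ ms below it (ties resolve to $\tau_1$; the choice only
affects the measure-zero point $V = 0$).  Inputs are gated by
$(V_\mathrm{sat}-V)/V_\mathrm{sat}$ (excitatory and noise) and
$(V_\mathrm{min}-V)/V_\mathrm{min}$ (inhibitory) with
$V_\mathrm{sat} = 90$ mV, $V_\mathrm{min} = -20$ mV, and the state is
clamped to $[V_\mathrm{min}, V_\mathrm{sat}]$, so membrane excursions stay
physiological by construction.

**Firing.**  A spike is emitted when $V \ge V_\mathrm{th}(t)$.  The
threshold rests at 6 mV; after a spike at $t_f$ it sits at $V_\mathrm{sat}$
for the absolute refractory period $t_a = 4$ ms and then relaxes back as
$6 + 84\,e^{-\kappa(t - t_f - t_a)}$ with $\kappa^{-1} = 0.5$ ms (relative
refractoriness).  During $t_a$ no spike is possible, which caps sustained
rates at $1/t_a = 250$ Hz — a property the suite asserts on saturating-drive
runs.  The membrane is *not* reset at a spike: only the threshold excursion
implements refractoriness.  A conventional reset variant is available
(`neurons$reset_on_spike`) but off by default, because the threshold
excursion alone reproduces the intended dynamics and a reset would be an
additional mechanism the model specification does not contain.

**Depressing synapses.**  Each presynaptic neuron carries one resource
fraction $x \in [0,1]$ (all of a neuron's outgoing synapses share its
axonal pool — with shared presynaptic spike trains, per-edge resources
would evolve identically anyway).  Between spikes
$\dot x = (1-x)/\tau_\mathrm{rec}$; at a spike a portion $U = 0.5$ of the
instantaneous resources is released, $x \leftarrow (1-U)x$, and the
released amount $U x$ (sampled *before* depletion) scales the postsynaptic
waveform.  Excitatory synapses inject a square pulse of width
$t_\mathrm{max}$ and peak $V_{0d}\,U x$ ($V_{0d} = 8$ mV); inhibitory
synapses inject a jump to $V_{0h}\,U x$ followed by exponential decay with
constant $\tau_2 = 26$ ms, with the balance convention
$V_{0h} = -4 V_{0d}$.  The pulse interval is half-open,
$[t_\mathrm{sp}, t_\mathrm{sp}+t_\mathrm{max})$ — the endpoint convention
is irrelevant at the integration step used but must be fixed for exact
streaming/brute-force equivalence.  $\tau_\mathrm{rec} = 0$ is the static
limit: resources recover instantly, every release equals $U$, and the
simulator must coincide *bit for bit* with a build whose depression factor
is hard-wired to $U$; the suite asserts exactly that.

**External drive.**  $V_\mathrm{noise}$ is an independent Poisson stream
per E neuron: events arrive at rate $\mu \cdot \mathrm{base\_rate}$ and
each injects a square depolarizing pulse of amplitude 5.48 mV and width
$t_\mathrm{max}$, summed into the excitatory gate but bypassing STD (the
afferents it models are not part of the simulated module).  By default only
E neurons receive drive — in the silent phase sporadic E events fail to
depolarize the I population, which receives its excitation exclusively
through the lattice; `noise$targets = "EI"` extends the drive to I for
sensitivity studies.

## Calibration of the two open constants

The reference parameter set fixes everything except the Poisson
`base_rate` (events/ms per neuron at $\mu = 1$) and the pulse width
`t_max`.  These are anchored by `calibrate_noise()` to two observable
targets: the silent-to-oscillatory onset must sit at $\mu = 0.5$ and the
no-depression spectrum at $\mu = 0.8$ must peak near 10 Hz (the alpha
rhythm).  Because the drive enters only through the product
$\mu \cdot \mathrm{base\_rate}$, the onset measured at any reference rate
rescales exactly; the rescaled rate is then *verified* on a fine onset scan
around the target and re-rescaled if needed — a coarse scan alone can
censor an onset lying below its first grid point, which is precisely the
failure mode the iteration guards against.  The two anchors pull the rate
in opposite directions (drive strong enough for a 10 Hz rhythm at
$\mu = 0.8$ implies an onset below 0.5), so a final joint stage scans
small upward rate scalings and minimises the worst tolerance-weighted
deviation from the two anchors, subject to one qualitative constraint of
the reference no-depression model: well-defined waves must persist as the
drive grows past the alpha point ($\mu = 1$ and $3$), which rejects
calibrations whose rhythm collapses just past onset, and the alpha peak is
measured as a seed-median because the $\mu = 0.8$ point can sit near a
regime boundary.

Calibration (seed 1) selects `t_max = 4` ms with `base_rate = 0.3026`
events/ms as shipped in `default_config()`, achieving an onset at
$\mu = 0.435$ and an alpha peak of 8.5 Hz — both anchors inside their
tolerances, neither exact.  The wide pulse is also the dynamically
sensible choice: at 1 ms candidates the I population receives such brief
EPSPs that the module desynchronizes at moderate noise instead of
shifting its rhythm upward in frequency.  Frequencies scale with drive
once `t_max` is fixed, so all remaining phenomenology — transition
locations in $\tau_\mathrm{rec}$, hysteresis, band content — consists of
predictions of the calibrated model, not fitted quantities.

## Numerical scheme

Forward Euler at $dt = 0.04$ ms, fixed by the definition of the absolute
refractory period as 100 steps.  The per-step error scale $dt/\tau
\approx 0.0025$ is negligible against the stochastic drive; the membrane
kernel is verified against closed-form exponential relaxation in the
suite.  Square pulses are implemented with per-neuron accumulators plus a
ring buffer of scheduled expiries (length $t_\mathrm{max}/dt + 1$), IPSPs
with a single multiplicative-decay accumulator per E neuron; both are
exactly equivalent to summing all past waveforms, which the suite checks
against brute-force summation on random spike schedules.  Spike effects
collected in a step are applied after all membranes have been updated, so
the update is order-independent within the population and a spike's
waveform first acts on the following step.  All randomness flows through
R's RNG: a run is bit-reproducible from its seed, and adiabatic sweeps
carry membrane state, resources, spike history *and* the RNG stream across
grid points (the backward branch continues from the forward end state).
The state is initialised at the unique parameter-free rest point: $V = 0$,
$x = 1$, no spike history.

The stepping loop is compiled (Rcpp); the exported R kernels
(`std_recover()`, `membrane_step()`, `threshold_at()`, ...) are the
readable reference implementations, and the tests pin the compiled path to
them (single-event propagation, static-limit identity, accumulator
equivalence).

## Analysis layer

The EEG proxy is the population-mean E membrane potential, sampled at
1 kHz (`record_stride = 25`).  Spectra use Welch's averaged periodogram:
Hann windows (default 2 s; 1.5 s inside sweeps, where each point
contributes 3 s of data), 50% overlap, per-segment linear detrending,
one-sided density normalisation.  Band powers integrate the density over
the standard clinical edges — delta 0.5–4, theta 4–8, alpha 8–13, beta
13–30, gamma 30–100 Hz — which partition the 0.5–100 Hz analysis range;
Parseval consistency against time-domain variance is asserted in the
suite.  Frequencies above 100 Hz remain visible in `frequencies`/`power`
(the module oscillates in the ultrafast band at very high drive), but peak
statistics and phase classification deliberately operate on the EEG range.

**Wave criterion.**  "A wave is present" is operationalised as: the
0.5–100 Hz spectral peak has prominence (peak power over the band median)
of at least 10, *and* at least 40% of the band power lies within
max(2 Hz, 20%) of the peak frequency.  Prominence alone cannot distinguish
a rhythm from the steep broadband low-frequency power of the incoherent
high-rate state beyond the depression transition: across a survey of 13
dynamical regimes, tonic states measured prominences of 24–59 (all
broadband) while genuine gamma rhythms measured 25–36.  Spectral
concentration separates the two cleanly (rhythms 0.45–0.60, broadband
0.09–0.31), so it is part of the criterion; both thresholds are
configurable and recorded in every serialized result.

**Transitions and phases.**  `detect_transition()` places a transition at
the largest jump of the order parameter (default: time-averaged mean E
potential) between consecutive grid points, independently per sweep
direction, and declares "no transition" when the largest jump is below 3
times the median inter-point change; hysteresis means forward and backward
locations differ by more than one grid step.  The detector is exact on
planted steps and loops, which the suite asserts.  Hysteresis calls are
dwell-sensitive: a dwell too short for the state to track its attractor
separates the forward and backward branches even across a continuous
transition, so hysteresis protocols use the full 5 s dwell and decide each
point by majority over seeds.  Phase labels follow
fixed observable rules — A (near-silent): mean E rate < 1 Hz; B (rhythm):
wave present and I rate ≥ 1 Hz; D (incoherent high excitation): I silent,
E rate ≥ 100 Hz, no wave; C (metastable): the two sweep directions
classify differently, with priority over the rest.  The 1 Hz silence and
100 Hz high-rate cutoffs are the conservative operational values used
throughout the analyses.

`oscillation_amplitude()` reports the mean peak-to-trough drop of the
band-passed (0.5–100 Hz, zero-phase 2nd-order Butterworth) proxy;
`low_high_coexistence()` quantifies slow/fast rhythm coexistence
(delta-theta against beta-gamma) by finding independent peaks in 0.5–8 Hz
and 13–100 Hz — each must exceed 3x its own range's median — plus the
delta+theta over beta+gamma power ratio.

## What the simulations show — and what they do not

The generator *is* the study system: a 196E/49I module with the reference
constants above.  Within it, the calibrated model reproduces the intended
phenomenology: an alpha peak near 10 Hz at $\mu = 0.8$ without depression;
a silent-to-oscillatory boundary at $\mu \approx 0.5$; rhythm frequency
increasing with drive; and, once $\tau_\mathrm{rec}$ is large enough,
depression of the E→I synapses silencing the I population and tipping the
module into tonic, incoherent E firing — abruptly and with hysteresis at
moderate-to-high drive.  Near that transition slow delta/theta components
coexist with the fast rhythm.

These are statements about the model, not about cortex: the module is
small (finite-size fluctuations are strong near boundaries), all neurons
share identical parameters, synaptic facilitation and E–E/I–I recurrence
are absent by design, the external world is reduced to independent Poisson
pulses, and the EEG proxy ignores volume conduction entirely.  Passing
tests demonstrate internal consistency and reproduction of the intended
dynamical regimes at the stated sizes; they do not validate the model
against recorded EEG.

Transition *locations* in $\tau_\mathrm{rec}$ carry an additional caveat:
they inherit the uncertainty of the two calibrated constants and of the
sweep protocol (dwell time per point), and first-order transition points in
finite stochastic systems are themselves fluctuation-broadened.  The
analysis therefore always reports them with the grid resolution and seed
spread, and the acceptance checks use correspondingly loose tolerances.

## Problem sizes

Simulated protocols used by the test suite and the acceptance script (all
on the default module unless stated): spectral anchors use 20 s of
recording after 2 s of settling; sweep protocols dwell 4-5 s per grid point,
discarding the first 2 s, with grids of 0.05 in $\mu$ and 5–10 ms in
$\tau_\mathrm{rec}$; stochastic anchors average 3–5 seeds.  Unit tests run
on an 8x8-E module with shorter traces, which keeps the full suite within
a few minutes while exercising every code path; the dynamical-anchor
checks always use the full default module.

## Known limitations

- The noise scale $\mu$ is defined only up to the calibrated `base_rate`;
  comparisons with other implementations must go through the two anchors,
  not raw $\mu$ values.
- `wave_present()` thresholds, though principled, are operational choices;
  phase-boundary positions shift by of order one grid step under
  reasonable variations.
- The tricritical region (where the first-order line turns continuous)
  requires fine two-dimensional hysteresis mapping beyond routine scale;
  the package exposes the machinery (`build_phase_diagram()`) but ships no
  precomputed fine diagram.
- Long sweeps at high drive are rate-limited by spike handling; expect
  roughly 5 s of wall clock per minute of simulated time on one core.
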