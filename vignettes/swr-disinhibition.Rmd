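---
title: "Disinhibition-based modelling of sharp wave-ripples: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disinhibition-based modelling of sharp wave-ripples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swrnet)
```

## The circuit and the two models

Sharp wave-ripples (SWRs) are brief (50-100 ms) episodes of elevated,
ripple-modulated network activity in hippocampal CA3.  `swrnet` implements a
disinhibition hypothesis for their generation: a population of pyramidal
cells (P) interacts with two interneuron classes, PV+ basket cells (B) and a
postulated "anti-SWR" class (A).  Outside SWRs, tonically active A cells hold
P and B down; when B cells become active they suppress A cells, releasing P
from inhibition — the circuit switches to a high-P/high-B, silent-A state
that we identify with a SWR.  Short-term depression of the B→A synapses
(efficacy `e`, depleted by B spikes, recovering with `tau_D = 250` ms)
terminates each event and imposes refractoriness.

Two model levels are provided:

* a **spiking network** of 8200 P, 135 B and 50 A conductance-based
  leaky integrate-and-fire neurons with random Bernoulli connectivity,
  exponentially decaying conductances (`tau_syn` = 2 / 1.5 / 4 ms for
  P / B / A synapses), 1 ms axonal delay, a 200 pA background drive, and
  presynaptically driven depression/facilitation;
* a **rate model** with one activity variable per population,
  `tau_I dI/dt = -I + f_I(sum of weighted inputs)`, a softplus activation
  `f_I(x) = F log(1 + exp(k_I (x + t_I)))`, and the same depression dynamics
  `de/dt = (1 - e)/tau_d - eta_d B e` acting on the B→A weight.

The rate model is not a convenience: it is *derived* from the spiking
network (section "Reduction") and is the object on which fixed-point and
continuation analysis becomes tractable.

## Spiking network numerics

The simulator is clock-driven with `dt = 0.1` ms by default.  Numerical
choices that matter:

* **Exponential-Euler conductances, forward-Euler membrane.** Conductances
  decay by the exact factor `exp(-dt/tau)` each step; the membrane potential
  is advanced with a forward step using the start-of-step conductances.
  Spike threshold crossings are detected at grid points and spike times are
  recorded on the grid (no interpolation): the grid is much finer than every
  time constant of interest, and the isolated-neuron firing rate matches the
  closed-form LIF expression to about 0.1% (see the test suite).
* **Charge-conserving delta delivery.** A presynaptic spike increments the
  postsynaptic conductance one delay later.  A naive jump of `g_unit`
  followed by stepwise decay carries total charge
  `g_unit dt / (1 - exp(-dt/tau))`, which overweights every synaptic event by
  about `dt/2tau` (2.5-3.4% at 0.1 ms) and biases fast excitation against
  slow inhibition.  The jump is therefore scaled by
  `tau (1 - exp(-dt/tau)) / dt`, so each event carries exactly the
  continuous-time charge `g_unit tau` at any step size.  With this choice,
  halving `dt` changes stationary population rates by less than 2%.
* **Delays** are per-synapse-type ring buffers; `dt` must divide every delay
  (enforced).  The efficacy factor that scales a spike's conductance jump is
  frozen at the spike time, not the arrival time.
* **Refractoriness** clamps the membrane at the reset potential for
  `t_refr = 1` ms; synaptic conductances keep integrating during that time
  (the conductance dynamics carry no refractory gating).
* **Initial conditions.** Membrane potentials start uniformly between rest
  and threshold, and conductances start at their stationary mean for assumed
  non-SWR rates (2, 1, 12 spikes/s).  A cold start (all conductances zero)
  sends every neuron towards threshold in near-synchrony, and whether the
  network then relaxes into the non-SWR or the SWR basin is a coin flip;
  initializing the conductances puts the run deterministically into the
  intended basin.  `init_rates = c(P = 0, B = 0, A = 0)` restores the cold
  start.
* **Randomness** comes from one master seed that spawns independent named
  streams (connectivity per synapse type, initial potentials, stimulus
  subsets, amplitudes and jitter), so changing a stimulation protocol does
  not perturb the realized connectivity.  Identical (seed, spec, stimuli,
  dt) replays bit-identically.

Short-term plasticity follows the presynaptic-spike-train formulation: all
synapses sharing a presynaptic neuron share one efficacy variable, which the
simulator exploits (one variable per presynaptic cell per plastic
projection).  Depression multiplies the efficacy by `1 - eta_D` at each
spike; facilitation adds `(z_max - z) eta_F` and scales the conductance by
`1 + z`.  When the normalized facilitation variant is used, conductances are
divided by `1 + z_nonSWR` with
`z_nonSWR = P0 z_max eta_F tau_F / (1 + P0 eta_F tau_F)` at the baseline P
rate `P0 = 2` spikes/s, so the connection keeps its nominal strength at
baseline.

## LFP proxy and event quantification

The field potential in stratum pyramidale is approximated by the synaptic
current from B onto P cells, sign-reversed and averaged across P cells — a
point-neuron stand-in justified by the perisomatic targeting of basket
cells.  The sharp-wave component is the proxy low-passed at 5 Hz, the ripple
component band-passed at 90-180 Hz, both with order-2 Butterworth filters
run forward-backward.  Zero-phase filtering is deliberate: event times must
not be phase-shifted by the filter (a causal filter would delay every
half-max crossing by several milliseconds).

Event detection takes strict local maxima of the sharp wave above 30 pA,
prunes peaks closer than 100 ms to a larger surviving peak (largest first),
and measures each event at half maximum, where the half level is the mean of
the peak amplitude and a common baseline (the across-event average of the
signal 200-100 ms before each peak).  Events without 200 ms of history are
excluded.  The inter-event interval runs from one event's *end* to the next
event's *start*, so IEIs shorter than the 100 ms peak separation are
possible.  The amplitude threshold is applied to the signal above zero, not
above baseline: in this model the sharp-wave baseline hovers near zero
outside events, and the baseline enters the width measurement instead.
Presets adjust the thresholds for the facilitation-only network
(40 pA / 200 ms) and for the noisy rate model (45 s^-1 on the 10 Hz
low-passed B rate).

The spectral peak of the ripple band is located with a Welch-averaged
periodogram (Hann window, 50% overlap, zero-padded FFT) restricted to
90-180 Hz; for event-locked estimates the per-event segments' spectra are
averaged.

## Reduction to the rate model

The reduction proceeds in three steps, each implemented as an exported
function:

1. **State-dependent f-I curves** (`measureFICurves`).  Because the clamped
   network is bistable, a single f-I curve per population is not enough: the
   synaptic input statistics differ drastically between states.  Read-only
   *clone* neurons — copies of randomly selected cells that inherit the full
   incoming connectivity but project nowhere — are driven by constant
   currents (grid -100 to 200 pA) while the network is held in the non-SWR
   or the SWR state (entered via a transient B depolarization with the B→A
   efficacy clamped at 0.5).  The clone's mean firing rate is recorded
   against its measured mean total input (external + background + synaptic),
   time-averaged after a 500 ms transient.  The clone contract — removing
   all clones leaves the network spike trains bit-identical — is enforced by
   construction and by test.  All grid currents run simultaneously (one
   clone set per grid value), which makes the measurement a single
   simulation instead of one per current.
2. **Empirical curve and softplus fit** (`assembleEmpiricalFI`,
   `fitSoftplus`).  The empirical curve uses the population's *inactive*
   state below a splice current and its *active* state above it, the splice
   point being the active-state mean input minus one SD (for A, whose active
   state is the non-SWR state, the roles are mirrored).  A softplus is then
   fitted by bounded least squares with `k` in [0, 2] 1/pA and `s` in
   [-100, 0] pA, uniform weights over grid points; the rate-model threshold
   absorbs the background current, `t = s + 200`.
3. **Weight mapping and membrane-potential optimization**
   (`weightsFromSpiking`, `optimizeMembranePotentials`).  The mapping
   `W_IJ = N_J p^IJ g^IJ tau_syn^J |E_rev^J - V_I|` needs one free quantity
   per population, the mean membrane potential `V_I`, which genuinely
   differs between states.  It is chosen by exhaustive grid search over
   [-60, -50] mV in 0.5 mV steps: each candidate triple is accepted only if
   the clamped (e = 0.5) rate model, stimulated through three paradigms
   (depolarizing P and B pulses, hyperpolarizing A pulse), shows the same
   two stable states with rates in a biologically sanctioned range (non-SWR:
   P, B < 5, A > 8; SWR: P > 8, B > 30, A < 5 s^-1), and the admissible
   triple minimizing the Euclidean distance to the spiking network's
   measured state rates is returned (ties resolve to the first point in
   lexicographic grid order).  The optimization targets default to the
   measured clamped-network rates (1.94, 1.32, 12.56) / (43.60, 91.87, 1.12)
   spikes/s rather than the round design values (2, 1, 12) / (43, 90, 1):
   the grid is selecting among rate models whose non-SWR A branch moves by
   about 0.3 s^-1 per 0.5 mV of `V_A`, so the optimum is only meaningful
   against the rates the spiking network actually attains.

For the noisy rate model, each of the nine presynaptic streams is modelled
as a homogeneous Poisson process at rate `N_pre p_conn rate_nonSWR(pre)`,
convolved with an exponential kernel of amplitude
`g_unit (E_rev_pre - V_post)` and decay `tau_syn_pre`, summed per target
population, mean-subtracted, and divided by 8.  The divisor compensates for
the spike-train correlations that the independent-Poisson construction
neglects (7 in the facilitation-only variant, whose noise must be slightly
stronger to trigger events).  Campbell's theorem gives the pre-subtraction
moments (`mean = rate a tau`, `var = rate a^2 tau / 2`), which the generator
reproduces and the tests check.  Rate ODEs are integrated with fixed-step
RK4 at `dt = 0.1` ms, noise and stimuli held constant within a step; noise
is pre-generated from a named stream so noisy runs replay exactly.

## Fixed points, continuation and pathway requirements

Steady states of the rate model solve `r = f(S r)` with the signed weight
matrix `S` (P excites; B and A inhibit; the B→A entry carries the efficacy
`e`, the A←P entry the facilitation factor `1 + z`).  The engine uses damped
Newton iteration with the analytic Jacobian from a fixed set of multi-start
seeds (origin-like, SWR-like, a coarse lattice) plus, during sweeps, the
previous parameter value's solutions (natural-parameter continuation).
Duplicates merge at 1e-5 relative tolerance; every reported point satisfies
a residual below 1e-8; stability comes from the eigenvalues of the ODE
Jacobian with `e` and `z` treated as parameters.  Fold locations are refined
by bisection on the fixed-point count to 1e-3 of the swept parameter.  For
the reference parameters the engine places the depression fold at
`e_crit ≈ 0.403`, the facilitation-variant bistability bound at
`z ≈ 0.665`, and finds no fold along the recurrent excitation `W_PP`.

That last case needs a policy.  Along `W_PP` the active branch grows without
bound: in the asymptotically linear regime the branch diverges where
`1 - k_P W_PP + k_P W_PB k_B W_BP / (1 + k_B W_BB)` crosses zero
(≈ 4.06 pA s for the defaults), so any finite-rate continuation stops
earlier, at a point set by its rate ceiling.  The engine truncates branches
at a blow-up cap of **1000 spikes/s** and reports the truncation point
(≈ 3.9 pA s for the defaults): 1000 s^-1 is `1/t_refr`, the absolute
refractory ceiling of the spiking neurons the rate model approximates, and
rate-model branches above it describe no attainable network state.  The cap
is a parameter (`cap`) for users who want the bare mathematical object.

Two-parameter bistable regions are computed by dense-grid classification of
the fixed-point count (three fixed points, two stable, marks bistability),
which is robust and trivially parallel at this problem size; the boundary is
extracted as a contour of the count.  The four circuit requirements
(activating P must suppress A and recruit B; activating B must disinhibit P;
silencing A must release P) are evaluated in the linear approximation
`f_I(x) ≈ F k_I (x + t_I)`: the strength of a direct pathway J→I is
`k_I w_IJ / (1 - k_I w_II)` with signed weights, an indirect pathway is the
product of its constituents, and each requirement becomes an explicit
inequality in the weights (listed in `?pathwayStrengths`).  Only the first
requirement has a canonical printed form; the other three are derived by the
same substitution, which is recorded here as the package's reading.

## The synthetic sharp-wave fixture

`makeSyntheticSWTrace` builds a trace of Gaussian bumps on a zero baseline
plus white noise, with the ground truth (times, amplitudes, widths)
recorded; a bump of width `sigma` has FWHM `2 sigma sqrt(2 log 2)`.  It
emulates exactly what the detector assumes — isolated, roughly
bell-shaped deflections with a stationary baseline — and deliberately not
what real sharp waves add on top (ripple-band structure, asymmetric rise and
decay, baseline drift, amplitude-dependent shape).  Passing the fixture
tests therefore validates the measurement pipeline (recall, amplitude and
width calibration, planted IEI-amplitude correlations), not the physiology
of the simulated events; the network-level tests do the latter.

## Problem sizes and stochastic tolerances

The test suite and the acceptance script use desk-scale problem sizes chosen
to keep full runs in minutes: 4-6.5 s windows for the clamped bistable
states, 3-minute spontaneous runs for event statistics (roughly 300-400
events each), 20 clones × 4 s per state and a 10 pA grid for the f-I
measurement, and 51-61 point sweeps for continuation.  Because the realized
connectivity of the 135-cell B population shifts the state rates by several
percent between network realizations, the acceptance script pools several
realizations (three for the clamped states, two spontaneous runs) instead of
reporting a single draw.  Quantities that are deterministic at fixed
parameters (weights, fixed points, folds) are asserted tightly; quantities
estimated from stochastic simulations carry tolerances matched to their
sampling variability at these sizes.

## Known limitations

* **Fluctuation-sensitive baselines.**  In the non-SWR state, B cells sit
  far below threshold on average and fire only on input fluctuations, and
  SWR initiation itself is a fluctuation-driven escape across the unstable
  threshold state.  Such exponential-tail quantities — the non-SWR B (and
  hence P) rate, the spontaneous incidence and hence the mean IEI, and the
  knife-edge excitability of the facilitation-only variant — respond
  strongly to percent-level differences in integration conventions that
  leave dt-convergence intact.  The package documents its conventions above
  precisely because reproducing tail-driven statistics across simulators is
  hard; attractor-level quantities (state rates under clamp, event
  amplitude and width, depression bounds, fold locations, weights) are
  robust.
* The LFP proxy ignores dendritic and A-cell contributions and cell
  morphology by construction; ripple-band results report the spectral peak
  of an oscillating inhibitory loop with a fixed 1 ms delay and are not a
  mechanistic model of ripple frequency.
* Populations are homogeneous and connectivity is unstructured Bernoulli;
  there are no cell assemblies, no distance dependence, and no
  heterogeneity in intrinsic parameters.
* The rate model approximates stationary behaviour only; its population
  time constants (3, 2, 6 ms) are set by hand and transients (including
  ripples) are outside its scope.
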