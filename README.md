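# swrnet

Spiking and rate models of sharp wave-ripple (SWR) generation by
disinhibition in a CA3-like hippocampal microcircuit.

Sharp wave-ripples are brief (50-100 ms) high-activity events that dominate
the hippocampal field potential during rest and slow-wave sleep and are
central to memory consolidation. `swrnet` implements a three-population
model of their generation: pyramidal cells (P), PV+ basket cells (B) and a
postulated class of tonically active "anti-SWR" interneurons (A). The
non-SWR state is governed by the P-A subnetwork; when B cells activate they
suppress A cells and *disinhibit* the pyramidal population, switching the
circuit into a high-P/high-B, silent-A state — a SWR. Short-term synaptic
depression of the B→A connection (efficacy `e`, depleted by B spikes at rate
`eta_D = 0.18`, recovering with `tau_D = 250 ms`) terminates each event and
sets the refractoriness and the inter-event statistics.

The package is aimed at computational neuroscientists who want to simulate
the circuit, quantify simulated SWRs the way experimentalists quantify
recorded ones, and analyse the underlying bistability:

* **Spiking network** — 8200 P / 135 B / 50 A conductance-based
  leaky integrate-and-fire neurons, random Bernoulli connectivity,
  1 ms delays, exponential synapses (`tau_syn` 2 / 1.5 / 4 ms),
  presynaptically driven depression and facilitation, flexible
  current-injection protocols, bit-reproducible under a master seed
  (`defaultNetworkSpec()`, `buildNetwork()`, `simulateNetwork()`,
  Rcpp core).
* **LFP proxy and event pipeline** — the sign-reversed mean B→P synaptic
  current stands in for the stratum pyramidale LFP; order-2 zero-phase
  Butterworth filters extract the sharp wave (≤ 5 Hz) and ripple
  (90-180 Hz) bands; events are detected at half maximum and summarized by
  amplitude, FWHM, inter-event intervals, their Pearson correlations and an
  exponential amplitude-recovery fit (`lfpProxy()`, `detectSWREvents()`,
  `eventStatistics()`, `ripplePeakFrequency()`).
* **Rate model** — `tau_I dI/dt = -I + f_I(...)` with softplus activations
  `f_I(x) = F log(1 + exp(k_I (x + t_I)))`, the weight mapping
  `W_IJ = N_J p^IJ g^IJ tau_syn^J |E_rev^J − V_I|`, dynamic depression and
  facilitation, and Poisson shot-noise inputs scaled down by a factor 8
  (`defaultRateParams()`, `weightsFromSpiking()`, `simulateRate()`,
  `generateSynapticNoise()`).
* **Reduction** — state-dependent f-I curves measured with read-only clone
  neurons, empirical-curve splicing, bounded softplus fits, and exhaustive
  grid optimization of the mean membrane potentials
  (`measureFICurves()`, `fitSoftplus()`, `optimizeMembranePotentials()`).
* **Bifurcation engine** — multi-start damped-Newton fixed points with
  analytic Jacobians, natural-parameter continuation with bisection-refined
  folds, two-parameter bistable regions, and the four disinhibition
  requirements evaluated as pathway-strength inequalities
  (`steadyStates()`, `continueParameter()`, `bistableRegion2d()`,
  `pathwayStrengths()`).

See the vignette (`vignettes/swr-disinhibition.Rmd`) for the model
definitions, the numerical choices and the design rationale.

## A worked example

Clamp the B→A efficacy at 0.5 and switch the network between its two stable
states by current injection:

```r
library(swrnet)

net <- buildNetwork(defaultNetworkSpec(clamp_eAB = 0.5), seed = 1)
tr  <- simulateNetwork(net, duration = 6500,
         stimuli = list(stimulusProtocol("P", fraction = 0.6,
                                         amplitude_max = 300,
                                         duration = 10, onsets = 1000)))
round(colMeans(tr$rates[tr$t > 1500, ]), 2)
#>     P     B     A
#> 46.88 97.14  0.65
```

Before the pulse the network rests in the non-SWR state (P ≈ 2.9, B ≈ 3.1,
A ≈ 11.9 spikes/s); the 10 ms depolarization of 60% of the P cells switches
it into the SWR state (P ≈ 47, B ≈ 96 spikes/s with A silenced), which
persists because the efficacy is clamped — the network is bistable.

With depression left dynamic, SWRs start and stop on their own. A one-minute
spontaneous run, quantified like an experimental recording:

```r
net <- buildNetwork(defaultNetworkSpec(), seed = 1)
tr  <- simulateNetwork(net, duration = 60000)
ev  <- detectSWREvents(lfpProxy(tr))
eventStatistics(ev)
#> <event_stats> 123 events, incidence 2.07 /s
#>   IEI 0.380 +/- 0.138 s | amplitude 67.12 +/- 0.33 | FWHM 107.3 +/- 0.2 ms
#>   r(amp, prev IEI) = 0.709 (p = 6.8e-20); r(amp, next IEI) = -0.071 (p = 0.44)
```

Each event is a ~107 ms sharp wave of ~67 pA whose amplitude is strongly
correlated with the *preceding* inter-event interval but not the following
one — the signature of the depression mechanism: long intervals let the B→A
efficacy recover further, so the next event rides on stronger disinhibition.

The bistability itself is best understood in the rate model:

```r
p <- defaultRateParams()
steadyStates(p, e = 0.5)            # non-SWR, threshold, SWR fixed points
continueParameter(p, "e", c(0, 1))
#> <bifurcation_diagram> e in [0, 1]: 441 branch points
#>   folds at: 0.4034
```

Below the fold at `e ≈ 0.40` only the non-SWR state exists; above it the SWR
state coexists with it. The depression variable slowly crosses this fold
during an event, which is what terminates it.

A thin command-line wrapper over the experiment protocols is installed at
`inst/exec/swr-run`, e.g.
`Rscript inst/exec/swr-run spontaneous --seed 1 --minutes 2 --out results/`.

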