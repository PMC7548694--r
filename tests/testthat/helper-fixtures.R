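# Shared fixtures.  Heavy full-size simulations used by several acceptance
# checks are computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# three isolated populations (no synapses), used for single-neuron oracles
isolated_spec <- function(nP = 1, nB = 1, nA = 1, I_BG = 200) {
  pops <- list(
    populationSpec("P", nP, E_rev_out = 0, tau_syn_out = 2),
    populationSpec("B", nB, E_rev_out = -70, tau_syn_out = 1.5),
    populationSpec("A", nA, E_rev_out = -70, tau_syn_out = 4))
  keys <- as.vector(outer(c("P", "B", "A"), c("P", "B", "A"),
                          function(a, b) paste0(a, b)))
  syn <- lapply(keys, function(k)
    synapseSpec(substr(k, 1, 1), substr(k, 2, 2), 0, 0))
  networkSpec(pops, syn, I_BG = I_BG)
}

# closed-form stationary rate of the LIF neuron under constant current I (pA):
# ISI = t_refr + tau ln(dV_inf / (dV_inf - (V_thr - V_rest)))
lif_rate <- function(I, g_L = 10, tau = 20, t_refr = 1, dV_thr = 10) {
  dV_inf <- I / g_L
  if (dV_inf <= dV_thr) return(0)
  1000 / (t_refr + tau * log(dV_inf / (dV_inf - dV_thr)))
}

# shrunken default network for fast mechanistic tests (not dynamically
# equivalent to the full-size network)
small_net <- function(seed = 1, scale = 0.05, clamp_eAB = NULL) {
  buildNetwork(defaultNetworkSpec(clamp_eAB = clamp_eAB, scale = scale), seed)
}

# full-size clamped network used by several acceptance checks
acc_clamped_nonswr <- function() cached("clamped_nonswr", {
  net <- buildNetwork(defaultNetworkSpec(clamp_eAB = 0.5), seed = 1)
  simulateNetwork(net, 6000)
})

acc_clamped_swr <- function() cached("clamped_swr", {
  net <- buildNetwork(defaultNetworkSpec(clamp_eAB = 0.5), seed = 1)
  simulateNetwork(net, 6500,
    stimuli = list(stimulusProtocol("P", 0.6, 300, 10, onsets = 1000)))
})

# 3-minute spontaneous run (dynamic B->A depression) shared by the
# event-statistics, ripple and efficacy-bound checks
acc_spontaneous <- function() cached("spontaneous", {
  net <- buildNetwork(defaultNetworkSpec(), seed = 1)
  tr <- simulateNetwork(net, 180000)
  lfp <- lfpProxy(tr)
  ev <- detectSWREvents(lfp)
  list(trace = tr, lfp = lfp, events = ev, stats = eventStatistics(ev))
})
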