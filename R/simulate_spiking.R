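## Network realization and clock-driven simulation.

#' Realize the random connectivity of a network
#'
#' Samples, for each of the nine connection types, an independent
#' Bernoulli(`p_conn`) draw per directed ordered pair (self-pairs excluded),
#' using a dedicated deterministic RNG stream per type.  The same seed always
#' yields the same adjacency.
#'
#' @param spec a [networkSpec()].
#' @param seed integer master seed.
#' @return an object of class `network_instance` with elements `spec`,
#'   `adjacency` (per type: 0-based CSR `offsets`/`targets`), `counts`
#'   (realized connection counts) and `seed`.
#' @export
buildNetwork <- function(spec, seed) {
  stopifnot(inherits(spec, "network_spec"))
  n <- vapply(spec$populations, `[[`, 0L, "n_cells")
  adjacency <- vector("list", 9)
  counts <- numeric(9)
  keys <- character(9)
  for (s in spec$synapses) {
    t <- .type_index(s$pre, s$post)
    a <- .cpp_sample_adjacency(
      n[[s$pre]], n[[s$post]], s$p_conn, s$pre == s$post,
      .stream_seed(seed, "connectivity") + t)
    adjacency[[t + 1L]] <- a
    counts[t + 1L] <- length(a$targets)
    keys[t + 1L] <- paste0(s$pre, s$post)
  }
  names(adjacency) <- names(counts) <- keys
  structure(list(spec = spec, adjacency = adjacency, counts = counts,
                 seed = seed, n = n),
            class = "network_instance")
}

#' @export
print.network_instance <- function(x, ...) {
  cat("<network_instance> seed:", x$seed, "\n  synapse counts:\n")
  print(x$counts)
  invisible(x)
}

#' Current-injection protocol
#'
#' Describes transient square-pulse current injections to a random subset of
#' one population.  At each onset, a fraction of the cells is selected and
#' each selected cell receives a constant current drawn uniformly between 0
#' and `amplitude_max` (negative `amplitude_max` gives hyperpolarizing
#' currents) for `duration` ms.  Onsets can be jittered by a uniform delay in
#' `[0, jitter_max]` and the stimulated subset can be redrawn per onset.
#'
#' @param target population name.
#' @param fraction fraction of cells stimulated, in `[0, 1]`.
#' @param amplitude_max maximal per-cell amplitude (pA); the mean injected
#'   current is `amplitude_max / 2`.
#' @param duration pulse length (ms).
#' @param onsets vector of onset times (ms), strictly increasing.
#' @param jitter_max maximal uniform additive delay per onset (ms).
#' @param resample_targets redraw the stimulated subset at every onset.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulusProtocol <- function(target, fraction = 0.6, amplitude_max,
                             duration = 10, onsets, jitter_max = 0,
                             resample_targets = TRUE) {
  target <- match.arg(target, POPS)
  stopifnot(fraction >= 0, fraction <= 1, duration > 0,
            all(diff(onsets) > 0), jitter_max >= 0)
  structure(list(target = target, fraction = fraction,
                 amplitude_max = amplitude_max, duration = duration,
                 onsets = onsets, jitter_max = jitter_max,
                 resample_targets = resample_targets),
            class = "stimulus_protocol")
}

# realize stimulus protocols into concrete per-onset (cells, amplitudes)
# using the master seed's dedicated streams
.realize_stimuli <- function(stimuli, n, seed) {
  out <- list()
  for (si in seq_along(stimuli)) {
    st <- stimuli[[si]]
    npop <- n[[st$target]]
    n_sel <- round(st$fraction * npop)
    if (n_sel == 0) next
    jit <- .with_rng(.stream_seed(seed, "stim_jitter") + si, {
      if (st$jitter_max > 0) runif(length(st$onsets), 0, st$jitter_max)
      else numeric(length(st$onsets))
    })
    idx0 <- .with_rng(.stream_seed(seed, "stim_subset") + si,
                      sample.int(npop, n_sel))
    amps <- .with_rng(.stream_seed(seed, "stim_amp") + si, {
      lapply(seq_along(st$onsets), function(k)
        runif(n_sel, min(0, st$amplitude_max), max(0, st$amplitude_max)))
    })
    idxs <- if (st$resample_targets && length(st$onsets) > 1) {
      .with_rng(.stream_seed(seed, "stim_subset") + si + 5000,
                lapply(seq_along(st$onsets), function(k)
                  sample.int(npop, n_sel)))
    } else {
      rep(list(idx0), length(st$onsets))
    }
    for (k in seq_along(st$onsets)) {
      out[[length(out) + 1L]] <- list(
        on_ms = st$onsets[k] + jit[k], duration_ms = st$duration,
        pop = match(st$target, POPS) - 1L,
        idx = as.integer(idxs[[k]] - 1L), amp = as.numeric(amps[[k]]))
    }
  }
  out
}

#' Simulate the spiking network
#'
#' Clock-driven integration of the conductance-based LIF network with
#' exponential-Euler conductance decay and forward-Euler membrane update.
#' Conductances jump by the (efficacy-scaled) unitary increase one delay
#' after each presynaptic spike; depression/facilitation variables are
#' updated at presynaptic spike times and relax continuously in between.
#' Membrane potentials are initialized uniformly between `V_rest` and `V_thr`
#' (a deterministic function of the network seed), which places the default
#' network in the non-SWR state after a short transient.
#'
#' @param net a [buildNetwork()] result.
#' @param duration simulated time (ms).
#' @param stimuli list of [stimulusProtocol()] objects.
#' @param dt integration step (ms); must divide all synaptic delays.
#' @param record_every sample traces every `record_every` steps
#'   (default 10, i.e. 1 ms at `dt = 0.1`).
#' @param record_spikes named list per population: neuron indices (1-based)
#'   whose spikes are stored, `"all"`, or omitted for none.  Population rate
#'   traces are always computed from all cells.
#' @param record_Vm like `record_spikes`, indices whose membrane potential is
#'   sampled.
#' @param rate_sigma Gaussian smoothing width for the stored rate traces (ms).
#' @param init_rates assumed stationary firing rates (spikes/s) used to set
#'   the initial synaptic conductances to their stationary means, so that the
#'   run starts inside the intended basin of attraction; defaults to the
#'   non-SWR rates.  Set to zeros for a cold start.
#' @param clamp_eAB optional override of `spec$clamp_eAB`.
#' @param seed optional override of the seed used for initial conditions and
#'   stimulus realization (defaults to the network seed).
#' @param clones internal: clone-neuron specification used by
#'   [measureFICurves()].
#' @param transient_ms accumulation transient for clone statistics (ms).
#' @return an object of class `simulation_trace` with sample times `t` (ms),
#'   smoothed `rates` (spikes/s, one column per population), raw bin `counts`,
#'   `curr_P` (mean synaptic input current onto P cells from P/B/A, pA),
#'   plasticity traces `eAB`, `ePB`, `zAP`, recorded `spikes` and `Vm`, and
#'   clone outputs when requested.
#' @export
simulateNetwork <- function(net, duration, stimuli = list(), dt = 0.1,
                            record_every = 10L, record_spikes = list(),
                            record_Vm = list(), rate_sigma = 3,
                            init_rates = c(P = 2, B = 1, A = 12),
                            clamp_eAB = NULL, seed = NULL, clones = NULL,
                            transient_ms = 500) {
  stopifnot(inherits(net, "network_instance"), duration > 0, dt > 0)
  spec <- net$spec
  n <- net$n
  if (is.null(seed)) seed <- net$seed
  if (is.null(clamp_eAB)) clamp_eAB <- spec$clamp_eAB

  g_unit <- delay <- numeric(9)
  dep_on <- fac_on <- clamp_on <- logical(9)
  dep_eta <- dep_tau <- fac_eta <- fac_tau <- numeric(9)
  fac_zmax <- fac_zinit <- numeric(9)
  fac_scale <- rep(1, 9)
  for (s in spec$synapses) {
    t <- .type_index(s$pre, s$post) + 1L
    g_unit[t] <- s$g_unit; delay[t] <- s$delay
    pl <- s$plasticity
    if (!is.null(pl) && pl$type == "depression") {
      dep_on[t] <- TRUE; dep_eta[t] <- pl$eta_D; dep_tau[t] <- pl$tau_D
    }
    if (!is.null(pl) && pl$type == "facilitation") {
      fac_on[t] <- TRUE; fac_eta[t] <- pl$eta_F; fac_tau[t] <- pl$tau_F
      fac_zmax[t] <- pl$z_max
      if (isTRUE(pl$normalize)) {
        z0 <- zNonSWR(pl$P0, pl$eta_F, pl$tau_F, pl$z_max)
        fac_scale[t] <- 1 / (1 + z0)
        fac_zinit[t] <- z0
      }
    }
    if (abs(round(s$delay / dt) * dt - s$delay) > 1e-9)
      stop("dt must divide the synaptic delay of ", s$pre, "->", s$post)
  }
  tAB <- .type_index("B", "A") + 1L
  if (!is.null(clamp_eAB)) {
    clamp_on[tAB] <- TRUE
  }
  clamp_val <- numeric(9)
  if (!is.null(clamp_eAB)) clamp_val[tAB] <- clamp_eAB

  cpp_net <- list(
    n = as.integer(n),
    C = vapply(spec$populations, `[[`, 0, "C"),
    g_L = vapply(spec$populations, `[[`, 0, "g_L"),
    V_rest = vapply(spec$populations, `[[`, 0, "V_rest"),
    V_thr = vapply(spec$populations, `[[`, 0, "V_thr"),
    V_reset = vapply(spec$populations, `[[`, 0, "V_reset"),
    t_refr = vapply(spec$populations, `[[`, 0, "t_refr"),
    E_rev = vapply(spec$populations, `[[`, 0, "E_rev_out"),
    tau_syn = vapply(spec$populations, `[[`, 0, "tau_syn_out"),
    g_unit = g_unit, delay = delay, adj = unname(net$adjacency),
    dep_on = dep_on, dep_eta = dep_eta, dep_tau = dep_tau,
    fac_on = fac_on, fac_eta = fac_eta, fac_tau = fac_tau,
    fac_zmax = fac_zmax, fac_scale = fac_scale, fac_zinit = fac_zinit,
    clamp_on = clamp_on, clamp_val = clamp_val,
    I_BG = spec$I_BG)

  # stationary mean conductance of type pre->post under Poisson presynaptic
  # firing: rate_pre * (N_pre p_conn) * g_unit * tau_syn_pre
  init_g <- vapply(spec$synapses, function(s) {
    pre <- spec$populations[[s$pre]]
    init_rates[[s$pre]] * pre$n_cells * s$p_conn * s$g_unit *
      pre$tau_syn_out / 1000
  }, 0)
  init_g_flat <- numeric(9)
  for (s in spec$synapses)
    init_g_flat[.type_index(s$pre, s$post) + 1L] <-
      init_g[[paste0(s$pre, s$post)]]

  init_V <- lapply(POPS, function(p) {
    ps <- spec$populations[[p]]
    .with_rng(.stream_seed(seed, "init_V") + match(p, POPS),
              runif(ps$n_cells, ps$V_rest, ps$V_thr))
  })

  pick_ids <- function(opt) {
    lapply(POPS, function(p) {
      v <- opt[[p]]
      if (is.null(v)) return(integer(0))
      if (identical(v, "all")) return(seq_len(n[[p]]) - 1L)
      as.integer(v - 1L)
    })
  }

  run <- list(duration = duration, dt = dt,
              record_every = as.integer(record_every),
              transient_ms = transient_ms, init_V = init_V,
              init_g = init_g_flat,
              stim = .realize_stimuli(stimuli, n, seed),
              rec_spikes = pick_ids(record_spikes),
              rec_Vm = pick_ids(record_Vm),
              clones = clones)

  raw <- .cpp_simulate(cpp_net, run)

  dt_sample <- dt * record_every
  rates <- sapply(1:3, function(p)
    .smooth_rate(raw$counts[, p], n[[p]], dt_sample, rate_sigma))
  colnames(rates) <- colnames(raw$counts) <- POPS
  colnames(raw$curr_P) <- POPS
  spikes <- lapply(1:3, function(p)
    data.frame(time = raw$spikes[[p]]$time, id = raw$spikes[[p]]$id + 1L))
  names(spikes) <- POPS
  out <- list(t = raw$t, dt = dt, dt_sample = dt_sample, duration = duration,
              n = n, rates = rates, counts = raw$counts, curr_P = raw$curr_P,
              eAB = raw$eAB, ePB = raw$ePB, zAP = raw$zAP,
              spikes = spikes, Vm = raw$Vm, rate_sigma = rate_sigma,
              seed = seed)
  if (!is.null(clones)) {
    out$clone_rate <- raw$clone_rate
    out$clone_curr_mean <- raw$clone_curr_mean
    out$clone_curr_sd <- raw$clone_curr_sd
  }
  structure(out, class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  mean_rates <- colMeans(x$rates)
  cat(sprintf(
    "<simulation_trace> %.0f ms (dt %.2g ms, sampled every %.2g ms)\n",
    x$duration, x$dt, x$dt_sample))
  cat(sprintf("  mean rates (spikes/s): P %.2f  B %.2f  A %.2f\n",
              mean_rates[1], mean_rates[2], mean_rates[3]))
  invisible(x)
}

## ---- rate traces and spike-train metrics ----

# Gaussian smoothing of binned spike counts -> population rate in spikes/s.
# Kernel truncated at +/- 4 sigma, normalized to unit mass, reflected edges,
# so the integral of rate * n_cells over time equals the total spike count.
.smooth_rate <- function(counts, n_cells, dt_sample, sigma) {
  rate <- counts / (n_cells * dt_sample / 1000)
  .gauss_smooth(rate, sigma / dt_sample)
}

.gauss_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_samples))
  k <- exp(-0.5 * ((-half:half) / sigma_samples)^2)
  k <- k / sum(k)
  n <- length(x)
  pad <- pmin(half, n - 1L)
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  y <- convolve(xp, rev(k), type = "filter")
  # convolve("filter") trims (length(k)-1)/2 from both ends of xp
  extra <- pad - half
  if (extra > 0) y <- y[(extra + 1):(length(y) - extra)]
  y
}

#' Smoothed population firing rate
#'
#' The per-neuron instantaneous rate, averaged over neurons and convolved
#' with a Gaussian kernel (width `sigma`, truncated at four standard
#' deviations, reflected boundaries).
#'
#' @param x a `simulation_trace` (uses the stored full-population spike-count
#'   bins), or a numeric vector of spike times (ms).
#' @param population population name (trace input).
#' @param sigma kernel width (ms).
#' @param n_neurons,duration,dt for spike-time input: population size,
#'   duration (ms) and bin width (ms).
#' @return for trace input, a numeric vector aligned with `x$t`; for spike
#'   input, a list with `t` and `rate`.
#' @export
populationRate <- function(x, population = NULL, sigma = 3, n_neurons = NULL,
                           duration = NULL, dt = 1) {
  if (inherits(x, "simulation_trace")) {
    stopifnot(population %in% POPS)
    return(.smooth_rate(x$counts[, population], x$n[[population]],
                        x$dt_sample, sigma))
  }
  stopifnot(sigma > 0, !is.null(n_neurons), n_neurons >= 1,
            !is.null(duration))
  if (length(x) && (min(x) < 0 || max(x) > duration))
    stop("spike times outside [0, duration]")
  nb <- ceiling(duration / dt)
  counts <- c(0, tabulate(pmin(pmax(ceiling(x / dt), 1L), nb), nbins = nb))
  list(t = (0:nb) * dt, rate = .smooth_rate(counts, n_neurons, dt, sigma))
}

#' Asynchrony/irregularity metrics
#'
#' Mean coefficient of variation of single-neuron inter-spike intervals
#' (averaged over neurons with at least two ISIs in the window) and the
#' standard deviation of the Gaussian-smoothed population rate over the same
#' window.  In the asynchronous-irregular regimen CV > 0.5 and the rate SD is
#' below 1 spike/s.
#'
#' @param trace a `simulation_trace` with spikes recorded for `population`.
#' @param population population name.
#' @param window `c(from, to)` in ms.
#' @param sigma smoothing width for the rate SD (ms).
#' @return list with `cv` and `rate_sd`.
#' @export
aiMetrics <- function(trace, population, window = NULL, sigma = 3) {
  sp <- trace$spikes[[population]]
  if (nrow(sp) == 0)
    stop("no spikes recorded for population ", population)
  if (is.null(window)) window <- c(0, trace$duration)
  sp <- sp[sp$time >= window[1] & sp$time <= window[2], ]
  cvs <- vapply(split(sp$time, sp$id), function(tt) {
    if (length(tt) < 3) return(NA_real_)
    isi <- diff(sort(tt))
    sd(isi) / mean(isi)
  }, 0)
  cvs <- cvs[!is.na(cvs)]
  if (!length(cvs)) stop("no neuron with at least two ISIs in the window")
  sel <- trace$t >= window[1] & trace$t <= window[2]
  rate <- populationRate(trace, population, sigma = sigma)
  list(cv = mean(cvs), rate_sd = sd(rate[sel]))
}

## ---- reference short-term plasticity updates ----

#' Short-term plasticity update rules
#'
#' Reference (scalar) implementations of the efficacy dynamics used by the
#' simulator: `depressionUpdate` advances a depression efficacy by one step
#' (`e <- e (1 - eta_D)` at a spike, relaxation towards 1 with `tau_D`
#' otherwise), `facilitationUpdate` advances a facilitation variable
#' (`z <- z + (z_max - z) eta_F` at a spike, decay towards 0 with `tau_F`).
#'
#' @param e,z current efficacy values.
#' @param spiked did the presynaptic neuron spike in this step?
#' @param dt step (ms).
#' @param eta_D,tau_D,eta_F,tau_F,z_max plasticity parameters (ms).
#' @return the updated efficacy.
#' @export
depressionUpdate <- function(e, spiked, dt, eta_D, tau_D) {
  stopifnot(all(e >= 0 & e <= 1))
  e <- 1 - (1 - e) * exp(-dt / tau_D)
  ifelse(spiked, e * (1 - eta_D), e)
}

#' Export recorded spikes as CSV
#'
#' Writes the recorded spikes of a simulation as a flat table with columns
#' `population`, `neuron_index`, `time_ms`.
#'
#' @param trace a `simulation_trace` with recorded spikes.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpikes <- function(trace, path) {
  tabs <- lapply(POPS, function(p) {
    sp <- trace$spikes[[p]]
    if (!nrow(sp)) return(NULL)
    data.frame(population = p, neuron_index = sp$id, time_ms = sp$time)
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname depressionUpdate
#' @export
facilitationUpdate <- function(z, spiked, dt, eta_F, tau_F, z_max = 1) {
  stopifnot(all(z >= 0 & z <= z_max))
  z <- z * exp(-dt / tau_F)
  ifelse(spiked, z + (z_max - z) * eta_F, z)
}
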