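## Three-population rate model: parameters, weight mapping, simulation and
## shot-noise input generation.  Units: s, pA, spikes/s; weights in pA*s.

#' Softplus activation function
#'
#' `f(x) = F log(1 + exp(k (x + t)))`, evaluated in a numerically stable way
#' for large |argument|.  The threshold `t` folds the 200 pA background
#' current of the spiking network into the activation (`t = s + 200`).
#'
#' @param x input current (pA).
#' @param k slope (1/pA).
#' @param t threshold (pA).
#' @param F rate scale (spikes/s).
#' @return firing rate (spikes/s).
#' @export
softplusActivation <- function(x, k, t, F = 1) {
  a <- k * (x + t)
  F * ifelse(a > 30, a + log1p(exp(-a)),
             ifelse(a < -30, exp(a), log1p(exp(a))))
}

#' Rate-model parameters
#'
#' The standard parameter set of the rate model: the nine connection
#' strengths `W[post, pre]` (pA s) obtained from the spiking network via
#' [weightsFromSpiking()] with the optimized membrane potentials, the fitted
#' softplus slopes/thresholds, the population time constants, and the
#' depression/facilitation constants.
#'
#' @param W 3x3 nonnegative weight matrix, rows = postsynaptic P/B/A,
#'   columns = presynaptic P/B/A (pA s).
#' @param k softplus slopes (1/pA).
#' @param t softplus thresholds (pA).
#' @param tau population time constants (s).
#' @param F rate scale (spikes/s).
#' @param eta_d,tau_d depression rate and time constant (s).
#' @param eta_f,tau_f,z_max facilitation parameters (facilitation variant).
#' @return an object of class `rate_params`.
#' @export
rateParams <- function(W, k, t, tau = c(P = 0.003, B = 0.002, A = 0.006),
                       F = 1, eta_d = 0.18, tau_d = 0.25, eta_f = 0.32,
                       tau_f = 0.23, z_max = 1) {
  W <- as.matrix(W)
  stopifnot(all(dim(W) == c(3, 3)), all(W >= 0), all(k >= 0), all(tau > 0),
            F > 0)
  dimnames(W) <- list(POPS, POPS)
  structure(list(W = W, k = stats::setNames(k, POPS),
                 t = stats::setNames(t, POPS),
                 tau = stats::setNames(tau, POPS), F = F,
                 eta_d = eta_d, tau_d = tau_d,
                 eta_f = eta_f, tau_f = tau_f, z_max = z_max),
            class = "rate_params")
}

#' @rdname rateParams
#' @export
defaultRateParams <- function() {
  W <- rbind(P = c(1.72, 1.24, 12.60),
             B = c(8.86, 3.24, 13.44),
             A = c(1.72, 5.67, 8.40))
  colnames(W) <- POPS
  rateParams(W, k = c(0.47, 0.41, 0.48), t = c(131.66, 131.96, 131.09))
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params> W (pA s, rows = post):\n")
  print(round(x$W, 3))
  cat(sprintf("  k = (%.2f, %.2f, %.2f) 1/pA; t = (%.2f, %.2f, %.2f) pA\n",
              x$k[1], x$k[2], x$k[3], x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Map spiking-network parameters to rate-model weights
#'
#' `W_IJ = N_J p^IJ g^IJ tau_syn^J |E_rev^J - V_I|`: presynaptic population
#' size times connection probability times unitary conductance times synaptic
#' time constant times driving force at the postsynaptic mean membrane
#' potential.  Inhibitory weights carry the sign flip so that all returned
#' weights are nonnegative; units resolve to pA s.
#'
#' @param spec a `network_spec`.
#' @param V named mean membrane potentials `c(P = , B = , A = )` (mV).
#' @return 3x3 weight matrix (post, pre) in pA s.
#' @export
weightsFromSpiking <- function(spec, V = c(P = -52.5, B = -54.0, A = -52.5)) {
  stopifnot(inherits(spec, "network_spec"), all(POPS %in% names(V)))
  W <- matrix(0, 3, 3, dimnames = list(POPS, POPS))
  for (s in spec$synapses) {
    pre <- spec$populations[[s$pre]]
    driving <- pre$E_rev_out - V[[s$post]]
    sgn <- if (s$pre == "P") 1 else -1
    w <- sgn * pre$n_cells * s$p_conn * s$g_unit * pre$tau_syn_out * driving
    # nS * ms * mV = pA * ms; convert to pA * s
    w <- w / 1000
    if (w < 0)
      stop("negative weight for ", s$pre, "->", s$post,
           ": V_", s$post, " on the wrong side of E_rev")
    W[s$post, s$pre] <- w
  }
  W
}

#' Rate-model parameters derived from a spiking specification
#'
#' @param spec a `network_spec`.
#' @param V mean membrane potentials (mV), see [weightsFromSpiking()].
#' @param k,t softplus parameters (defaults: the fitted values of the
#'   reference reduction).
#' @param ... passed to [rateParams()].
#' @return a `rate_params`.
#' @export
rateParamsFromSpiking <- function(spec, V = c(P = -52.5, B = -54.0, A = -52.5),
                                  k = c(0.47, 0.41, 0.48),
                                  t = c(131.66, 131.96, 131.09), ...) {
  rateParams(weightsFromSpiking(spec, V), k = k, t = t, ...)
}

#' Simulate the rate model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the population rates
#' (P, B, A), the depression efficacy `e` scaling the B->A weight, and
#' optionally the facilitation variable `z` scaling the A<-P weight by
#' `(1 + z)`.  Noise and stimuli enter the argument of the activation
#' function as currents held constant within a step.
#'
#' @param params a `rate_params`.
#' @param init initial rates `c(P, B, A)` (spikes/s).
#' @param duration simulated time (s).
#' @param dt step (s); must satisfy `dt <= min(tau) / 10`.
#' @param e0,z0 initial efficacy values.
#' @param e_clamp freeze `e` at this value (NULL: dynamic depression).
#' @param facilitation enable the `z` dynamics.
#' @param stimuli list of `list(target =, amplitude =, onset =, duration =)`
#'   square current pulses (pA, s).
#' @param noise 3 x n_steps matrix of input currents (pA), e.g. from
#'   [generateSynapticNoise()], or NULL.
#' @param record_every sample every this many steps.
#' @return an object of class `rate_trace`: `t` (s), `rates` (columns P/B/A),
#'   `e`, `z`.
#' @export
simulateRate <- function(params, init = c(0, 0, 0), duration, dt = 1e-4,
                         e0 = 1, z0 = 0, e_clamp = NULL,
                         facilitation = FALSE, stimuli = list(),
                         noise = NULL, record_every = 10L) {
  stopifnot(inherits(params, "rate_params"), duration > 0)
  if (dt > min(params$tau) / 10 + 1e-12)
    stop("dt must be at most min(tau)/10")
  stim <- lapply(stimuli, function(s) list(
    pop = match(s$target, POPS) - 1L, amp = s$amplitude,
    on_s = s$onset, off_s = s$onset + s$duration))
  if (is.null(noise)) noise <- matrix(0, 0, 0)
  e_dynamic <- is.null(e_clamp)
  raw <- .cpp_rate_simulate(
    params$W, params$k, params$t, params$tau, params$F,
    params$eta_d, params$tau_d, e_dynamic,
    if (e_dynamic) e0 else e_clamp,
    facilitation, params$eta_f, params$tau_f, params$z_max, z0,
    as.numeric(init), duration, dt, as.integer(record_every), noise, stim)
  colnames(raw$rates) <- POPS
  structure(list(t = raw$t, rates = raw$rates, e = raw$e, z = raw$z,
                 dt = dt, dt_sample = dt * record_every, duration = duration),
            class = "rate_trace")
}

#' @export
print.rate_trace <- function(x, ...) {
  fin <- nrow(x$rates)
  cat(sprintf(
    "<rate_trace> %.3g s; final (P, B, A) = (%.2f, %.2f, %.2f) s^-1, e = %.3f\n",
    x$duration, x$rates[fin, 1], x$rates[fin, 2], x$rates[fin, 3], x$e[fin]))
  invisible(x)
}

#' Shot-noise configuration from the spiking network
#'
#' For each of the nine (post, pre) pairs, the noise current is a Poisson
#' event train at rate `N_pre * p_conn * rate_nonSWR(pre)` convolved with an
#' exponential kernel of amplitude `g_unit (E_rev_pre - V_post)` and decay
#' `tau_syn_pre`, summed per postsynaptic population, mean-subtracted and
#' divided by a global divisor (8 by default; 7 in the facilitation-only
#' preset) that compensates for the neglected spike-train correlations.
#'
#' @param spec a `network_spec`.
#' @param V mean membrane potentials in the non-SWR state (mV).
#' @param rates_nonswr non-SWR firing rates of P/B/A (spikes/s).
#' @param divisor global noise divisor.
#' @return an object of class `noise_config` (data.frame of the nine pairs
#'   plus the divisor attribute).
#' @export
noiseConfigFromSpiking <- function(spec,
                                   V = c(P = -52.5, B = -54.0, A = -52.5),
                                   rates_nonswr = c(P = 1.94, B = 1.32,
                                                    A = 12.56),
                                   divisor = 8) {
  stopifnot(divisor > 0)
  rows <- lapply(spec$synapses, function(s) {
    pre <- spec$populations[[s$pre]]
    data.frame(post = s$post, pre = s$pre,
               rate = pre$n_cells * s$p_conn * rates_nonswr[[s$pre]],
               amplitude = s$g_unit * (pre$E_rev_out - V[[s$post]]),
               tau = pre$tau_syn_out / 1000)
  })
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            class = c("noise_config", "data.frame"), divisor = divisor)
}

#' Generate synaptic shot-noise currents
#'
#' Realizes the noise process described by a [noiseConfigFromSpiking()]
#' configuration on the simulation grid: per pair, Poisson counts per step
#' filtered with the exponential kernel (Campbell's theorem gives mean
#' `rate * amplitude * tau` and variance `rate * amplitude^2 * tau / 2`
#' before mean subtraction), summed per postsynaptic population,
#' mean-subtracted and divided by the configured divisor.
#'
#' @param cfg a `noise_config`.
#' @param duration duration (s).
#' @param dt step (s).
#' @param seed integer seed.
#' @return 3 x n_steps matrix of zero-mean currents (pA).
#' @export
generateSynapticNoise <- function(cfg, duration, dt = 1e-4, seed = 1) {
  stopifnot(inherits(cfg, "noise_config"))
  n_steps <- round(duration / dt)
  out <- matrix(0, 3, n_steps)
  divisor <- attr(cfg, "divisor")
  pair_mean <- pair_var <- numeric(nrow(cfg))
  for (i in seq_len(nrow(cfg))) {
    if (cfg$rate[i] <= 0 || cfg$amplitude[i] == 0) next
    counts <- .with_rng(.stream_seed(seed, "noise") + i,
                        rpois(n_steps, cfg$rate[i] * dt))
    # charge-conserving event amplitude: the zero-order-hold kernel carries
    # area a * dt / (1 - exp(-dt/tau)); rescale so each event integrates to
    # a * tau, making Campbell's moments exact at any dt
    decay <- exp(-dt / cfg$tau[i])
    a_eff <- cfg$amplitude[i] * cfg$tau[i] * (1 - decay) / dt
    shot <- stats::filter(a_eff * counts, decay, method = "recursive")
    shot <- as.numeric(shot)
    pair_mean[i] <- mean(shot)
    pair_var[i] <- stats::var(shot)
    p <- match(cfg$post[i], POPS)
    out[p, ] <- out[p, ] + shot
  }
  res <- (out - rowMeans(out)) / divisor
  # pre-subtraction per-pair moments (Campbell: mean = rate a tau,
  # var = rate a^2 tau / 2), kept for diagnostics and validation
  attr(res, "pair_mean") <- pair_mean
  attr(res, "pair_var") <- pair_var
  res
}
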