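## Network specification: populations, synapses, presets, (de)serialization.
## Units follow the parameter tables of the model: nS, mV, ms, pA, pF.

POPS <- c("P", "B", "A")

#' Population specification
#'
#' Intrinsic parameters of one homogeneous population of conductance-based
#' leaky integrate-and-fire neurons.  `E_rev_out` and `tau_syn_out` describe
#' the synapses this population *evokes* in its targets (reversal potential
#' and conductance decay depend on the presynaptic type only).
#'
#' @param name population label, one of `"P"`, `"B"`, `"A"`.
#' @param n_cells number of neurons (>= 1).
#' @param C membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param V_rest resting potential (mV).
#' @param V_thr spike threshold (mV).
#' @param V_reset reset potential (mV); must satisfy `V_reset <= V_thr`.
#' @param t_refr absolute refractory period (ms).
#' @param E_rev_out reversal potential of this population's outgoing synapses (mV).
#' @param tau_syn_out decay time constant of the conductances it evokes (ms).
#' @return an object of class `population_spec`.
#' @export
populationSpec <- function(name, n_cells, C = 200, g_L = 10, V_rest = -60,
                           V_thr = -50, V_reset = V_rest, t_refr = 1,
                           E_rev_out, tau_syn_out) {
  name <- match.arg(name, POPS)
  stopifnot(n_cells >= 1, V_reset <= V_thr, t_refr >= 0, tau_syn_out > 0,
            C > 0, g_L > 0)
  structure(list(name = name, n_cells = as.integer(n_cells), C = C, g_L = g_L,
                 V_rest = V_rest, V_thr = V_thr, V_reset = V_reset,
                 t_refr = t_refr, E_rev_out = E_rev_out,
                 tau_syn_out = tau_syn_out),
            class = "population_spec")
}

#' Synapse specification
#'
#' One directed connection type `pre -> post` with independent Bernoulli
#' connectivity, a fixed unitary conductance increase, a transmission delay,
#' and an optional short-term plasticity mechanism attached to the
#' presynaptic spike train.
#'
#' @param pre,post population names (`"P"`, `"B"`, `"A"`).
#' @param p_conn connection probability in `[0, 1]`.
#' @param g_unit unitary conductance increase (nS).
#' @param delay transmission delay (ms); must be a positive multiple of the
#'   integration step.
#' @param plasticity `NULL`, or a list created by [depression()] /
#'   [facilitation()].
#' @return an object of class `synapse_spec`.
#' @export
synapseSpec <- function(pre, post, p_conn, g_unit, delay = 1,
                        plasticity = NULL) {
  pre <- match.arg(pre, POPS); post <- match.arg(post, POPS)
  stopifnot(p_conn >= 0, p_conn <= 1, g_unit >= 0, delay > 0)
  if (!is.null(plasticity)) {
    stopifnot(inherits(plasticity, "stp_spec"))
    if (plasticity$type == "depression")
      stopifnot(plasticity$eta_D > 0, plasticity$eta_D < 1, plasticity$tau_D > 0)
    else
      stopifnot(plasticity$eta_F > 0, plasticity$eta_F < 1,
                plasticity$tau_F > 0, plasticity$z_max > 0)
  }
  structure(list(pre = pre, post = post, p_conn = p_conn, g_unit = g_unit,
                 delay = delay, plasticity = plasticity),
            class = "synapse_spec")
}

#' Short-term plasticity descriptors
#'
#' `depression()` describes presynaptically driven multiplicative depression:
#' each presynaptic spike scales the efficacy `e` by `(1 - eta_D)`, and `e`
#' relaxes back towards 1 with time constant `tau_D`.  `facilitation()`
#' describes a facilitation variable `z` that jumps by `(z_max - z) * eta_F`
#' at each presynaptic spike and decays towards 0 with `tau_F`; the evoked
#' conductance is scaled by `(1 + z)` (divided by `(1 + z_nonSWR)` when
#' `normalize = TRUE`, so that the connection keeps its nominal strength at
#' the baseline firing rate `P0`).
#'
#' @param eta_D,eta_F plasticity rates in `(0, 1)`.
#' @param tau_D,tau_F recovery/decay time constants (ms).
#' @param z_max upper bound of the facilitation variable.
#' @param normalize divide the conductance by `(1 + z_nonSWR)`.
#' @param P0 baseline presynaptic rate (spikes/s) used for `z_nonSWR`.
#' @return a list of class `stp_spec`.
#' @export
depression <- function(eta_D = 0.18, tau_D = 250) {
  structure(list(type = "depression", eta_D = eta_D, tau_D = tau_D),
            class = "stp_spec")
}

#' @rdname depression
#' @export
facilitation <- function(eta_F = 0.15, tau_F = 250, z_max = 1,
                         normalize = TRUE, P0 = 2) {
  structure(list(type = "facilitation", eta_F = eta_F, tau_F = tau_F,
                 z_max = z_max, normalize = normalize, P0 = P0),
            class = "stp_spec")
}

#' Baseline facilitation level at a given presynaptic rate
#'
#' The stationary mean of the facilitation variable under Poisson presynaptic
#' firing at `P0` spikes/s:
#' `z* = P0 z_max eta_F tau_F / (1 + P0 eta_F tau_F)` (time constants in
#' seconds).
#'
#' @param P0 presynaptic rate (spikes/s).
#' @param eta_F facilitation rate.
#' @param tau_F facilitation time constant (ms).
#' @param z_max upper bound of `z`.
#' @return the stationary facilitation level (dimensionless).
#' @export
zNonSWR <- function(P0, eta_F, tau_F, z_max = 1) {
  tf <- tau_F / 1000
  P0 * z_max * eta_F * tf / (1 + P0 * eta_F * tf)
}

#' Network specification
#'
#' A complete parameterization of the three-population spiking network:
#' exactly three populations (P, B, A) and the nine directed connection types
#' among them, plus the constant background drive.
#'
#' @param populations list of three [populationSpec()] objects (P, B, A).
#' @param synapses list of nine [synapseSpec()] objects covering every
#'   directed pair.
#' @param I_BG constant background current to every neuron (pA).
#' @param clamp_eAB optional value in `[0, 1]`: freeze all B->A efficacies at
#'   this value (disables the depression dynamics on B->A).
#' @return an object of class `network_spec`.
#' @export
networkSpec <- function(populations, synapses, I_BG = 200, clamp_eAB = NULL) {
  stopifnot(length(populations) == 3, length(synapses) == 9, is.finite(I_BG))
  names(populations) <- vapply(populations, `[[`, "", "name")
  if (!identical(sort(names(populations)), sort(POPS)))
    stop("populations must be exactly P, B and A")
  populations <- populations[POPS]
  keys <- vapply(synapses, function(s) paste0(s$pre, s$post), "")
  expected <- as.vector(outer(POPS, POPS, paste0))
  if (!setequal(keys, expected) || anyDuplicated(keys))
    stop("synapses must cover each of the nine directed pairs exactly once")
  names(synapses) <- keys
  synapses <- synapses[expected]
  if (!is.null(clamp_eAB)) stopifnot(clamp_eAB >= 0, clamp_eAB <= 1)
  structure(list(populations = populations, synapses = synapses, I_BG = I_BG,
                 clamp_eAB = clamp_eAB),
            class = "network_spec")
}

#' Default CA3-like network specification
#'
#' The standard parameter set of the model: 8200 P cells, 135 B cells
#' (PV+ basket cells) and 50 A cells (anti-SWR interneurons), with the nine
#' connection probabilities/conductances of the reference network and
#' short-term depression (eta_D = 0.18, tau_D = 250 ms) on B->A.
#'
#' @param clamp_eAB optional clamped B->A efficacy (see [networkSpec()]).
#' @param scale optional factor < 1 to shrink all population sizes (useful
#'   for quick tests; connection *probabilities* are unchanged, so scaled
#'   networks are not dynamically equivalent to the default one).
#' @return a `network_spec`.
#' @export
defaultNetworkSpec <- function(clamp_eAB = NULL, scale = 1) {
  pops <- list(
    populationSpec("P", max(1L, round(8200 * scale)), E_rev_out = 0,
                   tau_syn_out = 2),
    populationSpec("B", max(1L, round(135 * scale)), E_rev_out = -70,
                   tau_syn_out = 1.5),
    populationSpec("A", max(1L, round(50 * scale)), E_rev_out = -70,
                   tau_syn_out = 4))
  syn <- list(
    synapseSpec("P", "P", 0.01, 0.2),
    synapseSpec("P", "B", 0.20, 0.05),
    synapseSpec("P", "A", 0.01, 0.2),
    synapseSpec("B", "P", 0.50, 0.7),
    synapseSpec("B", "B", 0.20, 5),
    synapseSpec("B", "A", 0.20, 8, plasticity = depression(0.18, 250)),
    synapseSpec("A", "P", 0.60, 6),
    synapseSpec("A", "B", 0.60, 7),
    synapseSpec("A", "A", 0.60, 4))
  networkSpec(pops, syn, I_BG = 200, clamp_eAB = clamp_eAB)
}

#' Named variants of the network
#'
#' * `"default"`: B->A depression only.
#' * `"bp-depression"`: additional B->P depression with the same parameters
#'   as the B->A mechanism (eta_D = 0.18, tau_D = 250 ms).
#' * `"pa-facilitation"`: additional P->A facilitation (eta_F = 0.15,
#'   tau_F = 250 ms, z_max = 1) with baseline normalization by
#'   `(1 + z_nonSWR)`.
#' * `"facilitation-only"`: P->A facilitation is the only dynamic mechanism
#'   (eta_F = 0.32, tau_F = 230 ms, no normalization); B->A is clamped at
#'   e = 0.5 and the interneuron coupling is weakened (g_AB = 4.5 nS,
#'   g_BA = 5.5 nS) so that spontaneous events still occur.
#'
#' @param name preset name.
#' @param scale see [defaultNetworkSpec()].
#' @return a `network_spec`.
#' @export
networkPreset <- function(name = c("default", "bp-depression",
                                   "pa-facilitation", "facilitation-only"),
                          scale = 1) {
  name <- match.arg(name)
  spec <- defaultNetworkSpec(scale = scale)
  switch(name,
    "default" = spec,
    "bp-depression" = {
      spec$synapses$BP$plasticity <- depression(0.18, 250)
      spec
    },
    "pa-facilitation" = {
      spec$synapses$PA$plasticity <- facilitation(0.15, 250, 1,
                                                  normalize = TRUE, P0 = 2)
      spec
    },
    "facilitation-only" = {
      spec$synapses$BA$g_unit <- 4.5
      spec$synapses$AB$g_unit <- 5.5
      spec$synapses$PA$plasticity <- facilitation(0.32, 230, 1,
                                                  normalize = FALSE)
      spec$clamp_eAB <- 0.5
      spec
    })
}

#' @export
print.network_spec <- function(x, ...) {
  n <- vapply(x$populations, `[[`, 0L, "n_cells")
  cat("<network_spec> P/B/A sizes:", paste(n, collapse = "/"),
      " I_BG:", x$I_BG, "pA\n")
  for (s in x$synapses) {
    pl <- if (is.null(s$plasticity)) "" else paste0(" [", s$plasticity$type, "]")
    cat(sprintf("  %s->%s  p=%.2f g=%.2f nS delay=%g ms%s\n",
                s$pre, s$post, s$p_conn, s$g_unit, s$delay, pl))
  }
  if (!is.null(x$clamp_eAB))
    cat("  B->A efficacy clamped at", x$clamp_eAB, "\n")
  invisible(x)
}

#' Read / write a network specification
#'
#' Serializes a `network_spec` to JSON with keys mirroring the parameter-table
#' names (`N_P`, `p_AB`, `g_PB`, `tau_D`, ...), units as in the tables
#' (nS, mV, ms, pA).  Note the table convention: `p_AB` is the probability of
#' the connection B->A (superscript order is post, pre).
#'
#' @param spec a `network_spec`.
#' @param path file path.
#' @return `readNetworkSpec` returns a `network_spec`;
#'   `writeNetworkSpec` returns `path` invisibly.
#' @export
writeNetworkSpec <- function(spec, path) {
  pops <- lapply(spec$populations, function(p) p[setdiff(names(p), "name")])
  syns <- lapply(spec$synapses, function(s) {
    out <- list(p = s$p_conn, g = s$g_unit, delay = s$delay)
    if (!is.null(s$plasticity)) out$plasticity <- unclass(s$plasticity)
    out
  })
  # table-style naming: key "AB" = connection B->A
  names(syns) <- vapply(spec$synapses, function(s) paste0(s$post, s$pre), "")
  obj <- list(populations = pops, synapses = syns, I_BG = spec$I_BG,
              clamp_eAB = spec$clamp_eAB)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeNetworkSpec
#' @export
readNetworkSpec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pops <- lapply(POPS, function(nm) {
    p <- obj$populations[[nm]]
    populationSpec(nm, p$n_cells, C = p$C, g_L = p$g_L, V_rest = p$V_rest,
                   V_thr = p$V_thr, V_reset = p$V_reset, t_refr = p$t_refr,
                   E_rev_out = p$E_rev_out, tau_syn_out = p$tau_syn_out)
  })
  syns <- lapply(names(obj$synapses), function(key) {
    s <- obj$synapses[[key]]
    post <- substr(key, 1, 1); pre <- substr(key, 2, 2)
    pl <- NULL
    if (!is.null(s$plasticity)) {
      p <- s$plasticity
      pl <- if (p$type == "depression") depression(p$eta_D, p$tau_D)
            else facilitation(p$eta_F, p$tau_F, p$z_max, p$normalize,
                              if (is.null(p$P0)) 2 else p$P0)
    }
    synapseSpec(pre, post, s$p, s$g, s$delay, pl)
  })
  clamp <- obj$clamp_eAB
  if (!is.null(clamp) && (length(clamp) == 0 || is.na(clamp))) clamp <- NULL
  networkSpec(pops, syns, I_BG = obj$I_BG, clamp_eAB = clamp)
}

## ---- internal helpers ----

# index of synapse type in the flat pre*3+post layout used by the C++ core
.type_index <- function(pre, post) {
  (match(pre, POPS) - 1L) * 3L + (match(post, POPS) - 1L)
}

# derive a per-stream seed from a master seed; streams are decoupled so that
# changing e.g. a stimulation protocol does not perturb the connectivity
.stream_seed <- function(master, stream) {
  offs <- c(connectivity = 1, init_V = 101, stim_subset = 211,
            stim_amp = 307, stim_jitter = 401, noise = 503, clone = 601,
            fixture = 701)
  if (!stream %in% names(offs)) stop("unknown RNG stream: ", stream)
  (as.double(master) %% 2^31) * 2097169 + offs[[stream]] * 7919
}

# run code with a temporarily seeded R RNG, restoring the caller's state
.with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
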