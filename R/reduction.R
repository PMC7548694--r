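## Reduction of the spiking network to the rate model: state-dependent f-I
## curves measured with read-only clone neurons, empirical-curve assembly,
## bounded softplus fitting, and grid optimization of the mean membrane
## potentials used by the weight mapping.

#' Measure a state-dependent mean f-I curve
#'
#' Adds read-only "clone" neurons to the network: copies of randomly selected
#' cells of one population that inherit the full incoming connectivity of
#' their source cell but project nowhere, so the recurrent dynamics is
#' untouched.  Each clone set is driven by one constant external current from
#' `currents`, simultaneously for all grid values, while the network is held
#' in the requested state (the SWR state is entered via a transient
#' depolarization of B cells with the B->A efficacy clamped).  The returned
#' curve relates the measured mean total input current (external + background
#' + synaptic, time-averaged after a 500 ms transient) to the mean firing
#' rate of the clones.
#'
#' @param net a `network_instance`.
#' @param state `"non-SWR"` or `"SWR"`.
#' @param population population whose f-I curve is measured.
#' @param currents external current grid (pA).
#' @param n_clones clones per grid value.
#' @param T measurement window per grid value (s).
#' @param clamp_eAB clamped B->A efficacy used to hold the state.
#' @param seed RNG seed for clone-source selection (defaults to the network
#'   seed).
#' @param dt integration step (ms).
#' @return an object of class `fi_curve`: data.frame with `current_ext`,
#'   `input_mean` (measured mean total input, pA) and `rate` (spikes/s);
#'   attributes `state`, `population`, `input_mean0`/`input_sd0` (input
#'   statistics experienced in the state, from the zero-external-current
#'   clones).
#' @export
measureFICurves <- function(net, state = c("non-SWR", "SWR"), population = "B",
                            currents = seq(-100, 200, by = 5), n_clones = 50,
                            T = 20, clamp_eAB = 0.5, seed = NULL, dt = 0.1) {
  state <- match.arg(state)
  population <- match.arg(population, POPS)
  stopifnot(inherits(net, "network_instance"), n_clones >= 1, T > 0)
  if (is.null(seed)) seed <- net$seed
  if (!0 %in% currents) currents <- sort(c(0, currents))
  n_cur <- length(currents)
  npop <- net$n[[population]]

  sources <- .with_rng(.stream_seed(seed, "clone"),
                       sample.int(npop, min(n_clones, npop)))
  n_clones <- length(sources)
  n_total <- n_clones * n_cur
  clone_pop <- rep(match(population, POPS) - 1L, n_total)
  clone_Iext <- rep(currents, each = n_clones)

  # invert the network adjacency restricted to the source neurons and
  # replicate each in-edge across the current grid
  cadj <- vector("list", 9)
  for (t in 0:8) {
    post <- POPS[t %% 3 + 1]
    n_pre <- net$n[[POPS[t %/% 3 + 1]]]
    if (post != population) {
      cadj[[t + 1]] <- list(offsets = integer(n_pre + 1), targets = integer(0))
      next
    }
    a <- net$adjacency[[t + 1]]
    pre_of_edge <- rep(seq_len(n_pre) - 1L, diff(a$offsets))
    m <- match(a$targets, sources - 1L)
    sel <- which(!is.na(m))
    pre_sel <- pre_of_edge[sel]
    src_rank <- m[sel] - 1L
    reps <- rep(seq_len(length(sel)), each = n_cur)
    cid <- rep(src_rank, each = n_cur) +
      rep.int(0:(n_cur - 1), length(sel)) * n_clones
    pre_rep <- pre_sel[reps]
    ord <- order(pre_rep)
    cadj[[t + 1]] <- list(
      offsets = c(0L, cumsum(tabulate(pre_rep + 1L, nbins = n_pre))),
      targets = as.integer(cid[ord]))
  }

  stimuli <- list()
  t_stim <- 0
  if (state == "SWR") {
    t_stim <- 100
    stimuli <- list(stimulusProtocol("B", 0.6, 500, 10, onsets = t_stim))
  }
  transient <- 500 + t_stim
  duration <- transient + T * 1000

  tr <- simulateNetwork(net, duration = duration, stimuli = stimuli, dt = dt,
                        clamp_eAB = clamp_eAB,
                        clones = list(pop = clone_pop, Iext = clone_Iext,
                                      adj = cadj),
                        transient_ms = transient, seed = seed)

  win <- tr$t > transient
  mr <- colMeans(tr$rates[win, ])
  in_state <- if (state == "SWR") {
    mr[["P"]] > 8 && mr[["B"]] > 30 && mr[["A"]] < 5
  } else {
    mr[["P"]] < 5 && mr[["B"]] < 5 && mr[["A"]] > 8
  }
  if (!in_state)
    stop(sprintf(
      "network did not maintain the %s state during the measurement (P/B/A = %.1f/%.1f/%.1f)",
      state, mr[["P"]], mr[["B"]], mr[["A"]]))

  grp <- rep(seq_len(n_cur), each = n_clones)
  rate <- tapply(tr$clone_rate, grp, mean)
  input <- tapply(tr$clone_curr_mean, grp, mean)
  zero <- which(grp == match(0, currents))
  # combined across-time-and-neurons moments from per-clone (mean, sd)
  m0 <- mean(tr$clone_curr_mean[zero])
  v0 <- mean(tr$clone_curr_sd[zero]^2 + tr$clone_curr_mean[zero]^2) - m0^2
  out <- data.frame(current_ext = currents, input_mean = as.numeric(input),
                    rate = as.numeric(rate))
  structure(out, class = c("fi_curve", "data.frame"), state = state,
            population = population, input_mean0 = m0,
            input_sd0 = sqrt(max(v0, 0)), n_clones = n_clones, T = T)
}

#' Splice two state-dependent f-I curves into one empirical curve
#'
#' For P and B (whose "active" state is the SWR state) the empirical curve
#' uses the non-SWR curve below the splice current and the SWR curve above
#' it; the splice current is the SWR-state mean input minus one standard
#' deviation.  For A (active in the non-SWR state) the roles are reversed:
#' the SWR-state curve is used below the splice point (non-SWR mean input
#' minus one SD) and the non-SWR curve above.
#'
#' @param curve_nonswr,curve_swr `fi_curve` objects for the two states, on
#'   the same external-current grid.
#' @return data.frame with `input` (pA) and `rate` (spikes/s); attribute
#'   `splice` (pA).
#' @export
assembleEmpiricalFI <- function(curve_nonswr, curve_swr) {
  stopifnot(identical(attr(curve_nonswr, "population"),
                      attr(curve_swr, "population")),
            identical(curve_nonswr$current_ext, curve_swr$current_ext))
  pop <- attr(curve_nonswr, "population")
  if (pop %in% c("P", "B")) {
    splice <- attr(curve_swr, "input_mean0") - attr(curve_swr, "input_sd0")
    lo <- curve_nonswr; hi <- curve_swr
  } else {
    splice <- attr(curve_nonswr, "input_mean0") - attr(curve_nonswr, "input_sd0")
    lo <- curve_swr; hi <- curve_nonswr
  }
  x <- c(lo$input_mean[lo$input_mean < splice],
         hi$input_mean[hi$input_mean >= splice])
  y <- c(lo$rate[lo$input_mean < splice], hi$rate[hi$input_mean >= splice])
  if (!any(lo$input_mean < splice) || !any(hi$input_mean >= splice))
    stop("splice point lies outside the measured input range")
  ord <- order(x)
  structure(data.frame(input = x[ord], rate = y[ord]), splice = splice,
            population = pop)
}

#' Fit a softplus activation function
#'
#' Bounded least squares of `rate = F log(1 + exp(k (input + s)))` with
#' `k` constrained to `[0, 2]` (1/pA) and `s` to `[-100, 0]` (pA).  The
#' rate-model threshold folds the 200 pA background current into the fit:
#' `t = s + 200`.
#'
#' @param curve data.frame with `input` (total current, pA) and `rate`
#'   (spikes/s), e.g. from [assembleEmpiricalFI()].
#' @param F rate scale (spikes/s).
#' @return list with `k`, `s`, `t = s + 200`, `residual` (sum of squares) and
#'   `degenerate` (TRUE when the fit sits on the k = 0 boundary).
#' @export
fitSoftplus <- function(curve, F = 1) {
  stopifnot(nrow(curve) >= 5)
  df <- data.frame(x = curve$input, y = curve$rate)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ softplusActivation(x, k, s, F = F), data = df,
                      start = list(k = 0.5, s = -70),
                      lower = c(k = 0, s = -100), upper = c(k = 2, s = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("softplus fit did not converge: ",
                             conditionMessage(e)))
  co <- coef(fit)
  list(k = unname(co["k"]), s = unname(co["s"]), t = unname(co["s"]) + 200,
       residual = sum(stats::residuals(fit)^2),
       degenerate = unname(co["k"] < 1e-3 || max(df$y) <= 1e-8))
}

#' Optimize the mean membrane potentials of the weight mapping
#'
#' Exhaustive grid search over `(V_P, V_B, V_A)`.  For each combination the
#' nine weights are computed via [weightsFromSpiking()], and the clamped
#' (e = 0.5) rate model is simulated under three stimulation paradigms
#' (depolarizing pulses to P and to B, hyperpolarizing pulse to A).  A
#' combination is admissible when the same two stable states exist in all
#' three paradigms and both states fall into the biological range (non-SWR:
#' P < 5, B < 5, A > 8; SWR: P > 8, B > 30, A < 5 spikes/s).  Among the
#' admissible combinations, the one minimizing the Euclidean distance between
#' the achieved 6-vector of rates and `targets` is returned (ties resolved to
#' the first combination in lexicographic grid order).
#'
#' @param spec a `network_spec`.
#' @param activation list with `k` and `t` (length-3, order P/B/A).
#' @param targets 6-vector of target rates (non-SWR P/B/A, SWR P/B/A,
#'   spikes/s); defaults to the reference-state rates of the spiking network.
#' @param V_grid candidate membrane potentials (mV).
#' @param e clamped efficacy.
#' @param pulses named amplitudes of the three paradigm pulses (pA).
#' @param bio_ranges admissibility bounds, see above.
#' @param dt rate-model step (s).
#' @return an object of class `reduction_result`: optimized `V`, achieved and
#'   target rates, objective value, and the number of admissible grid points.
#' @export
optimizeMembranePotentials <- function(
    spec, activation,
    targets = c(1.94, 1.32, 12.56, 43.60, 91.87, 1.12),
    V_grid = seq(-60, -50, by = 0.5), e = 0.5,
    pulses = c(P = 100, B = 150, A = -200),
    bio_ranges = list(nonswr = list(P = c(-Inf, 5), B = c(-Inf, 5),
                                    A = c(8, Inf)),
                      swr = list(P = c(8, Inf), B = c(30, Inf),
                                 A = c(-Inf, 5))),
    dt = 2e-4) {
  stopifnot(all(is.finite(targets)), length(targets) == 6)
  k <- activation$k; t_thr <- activation$t
  best <- NULL
  n_admissible <- 0L
  in_range <- function(r, rng)
    r[1] > rng$P[1] && r[1] < rng$P[2] && r[2] > rng$B[1] && r[2] < rng$B[2] &&
    r[3] > rng$A[1] && r[3] < rng$A[2]

  for (vP in V_grid) for (vB in V_grid) for (vA in V_grid) {
    V <- c(P = vP, B = vB, A = vA)
    W <- tryCatch(weightsFromSpiking(spec, V), error = function(e) NULL)
    if (is.null(W)) next
    params <- rateParams(W, k = k, t = t_thr)
    states <- matrix(NA_real_, 6, 3)
    ok <- TRUE
    for (pi in 1:3) {
      st <- list(target = POPS[pi], amplitude = pulses[[POPS[pi]]],
                 onset = 0.25, duration = 0.01)
      trc <- simulateRate(params, duration = 0.8, dt = dt, e_clamp = e,
                          stimuli = list(st), record_every = 25L)
      pre <- colMeans(trc$rates[trc$t > 0.20 & trc$t <= 0.25, , drop = FALSE])
      post <- colMeans(trc$rates[trc$t > 0.70, , drop = FALSE])
      if (!in_range(pre, bio_ranges$nonswr) || !in_range(post, bio_ranges$swr)) {
        ok <- FALSE; break
      }
      states[, pi] <- c(pre, post)
    }
    if (!ok) next
    # the same two stable states must exist in all three paradigms
    if (max(apply(states, 1, function(x) diff(range(x)))) > 1) next
    n_admissible <- n_admissible + 1L
    achieved <- rowMeans(states)
    obj <- sqrt(sum((achieved - targets)^2))
    if (is.null(best) || obj < best$objective)
      best <- list(V = V, achieved = achieved, objective = obj)
  }
  if (is.null(best))
    stop("no admissible (V_P, V_B, V_A) combination satisfies the biological ",
         "ranges in all three stimulation paradigms")
  structure(list(V = best$V, k = stats::setNames(k, POPS),
                 t = stats::setNames(t_thr, POPS),
                 achieved = best$achieved, targets = targets,
                 objective = best$objective, n_admissible = n_admissible),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction_result> V = (%.1f, %.1f, %.1f) mV, objective %.3f (%d admissible)\n",
              x$V[1], x$V[2], x$V[3], x$objective, x$n_admissible))
  cat("  achieved rates:", paste(sprintf("%.2f", x$achieved), collapse = ", "),
      "\n")
  invisible(x)
}

#' Full reduction pipeline
#'
#' Measures the non-SWR and SWR f-I curves of each population, assembles the
#' empirical curves, fits the softplus activation functions and optimizes the
#' membrane potentials, yielding a complete [rateParams()] set.
#'
#' @inheritParams measureFICurves
#' @param populations populations to reduce.
#' @param ... passed to [optimizeMembranePotentials()].
#' @return list with per-population `fits`, the `reduction_result`, and the
#'   resulting `rate_params`.
#' @export
reduceNetwork <- function(net, currents = seq(-100, 200, by = 5),
                          n_clones = 50, T = 20, clamp_eAB = 0.5,
                          seed = NULL, populations = POPS, ...) {
  fits <- list()
  for (p in populations) {
    lo <- measureFICurves(net, "non-SWR", p, currents, n_clones, T,
                          clamp_eAB, seed)
    hi <- measureFICurves(net, "SWR", p, currents, n_clones, T,
                          clamp_eAB, seed)
    fits[[p]] <- fitSoftplus(assembleEmpiricalFI(lo, hi))
  }
  act <- list(k = vapply(fits, `[[`, 0, "k"), t = vapply(fits, `[[`, 0, "t"))
  red <- optimizeMembranePotentials(net$spec, act, ...)
  params <- rateParams(weightsFromSpiking(net$spec, red$V), k = act$k,
                       t = act$t)
  list(fits = fits, optimization = red, params = params)
}
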