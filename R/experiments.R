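## Figure-level experiment protocols and synthetic sharp-wave fixtures.

.digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

.periodic_pulses <- function(duration_ms, period_ms = 2000, first = 1000) {
  seq(first, duration_ms - 500, by = period_ms)
}

#' Run a named experiment protocol
#'
#' Reproducible end-to-end protocols tying together network construction,
#' simulation, LFP/event analysis and the rate/bifurcation machinery:
#'
#' * `bistable_clamp`: B->A efficacy clamped at 0.5; depolarizing pulse to P
#'   switches to the SWR state, hyperpolarizing pulse restores the non-SWR
#'   state; returns the trace and the two state rate vectors.
#' * `spontaneous` / `long_run_stats`: spontaneous run with dynamic B->A
#'   depression (default 1 / 10 minutes) and full event statistics.
#' * `evoked_P`, `evoked_B`, `evoked_A_hyper`: spontaneous run plus pulses
#'   every ~2 s (uniform per-cell amplitudes up to 300 / 600 / -500 pA to 60%
#'   of the cells, 10 ms, onset jitter uniform in [0, 90] ms).
#' * `bp_depression`, `pa_facilitation`, `facilitation_only`: the preset
#'   variants, analysed like `spontaneous` (the facilitation-only preset uses
#'   its 40 pA / 200 ms detection thresholds).
#' * `rate_noise`: the noisy rate model (spontaneous events detected on the
#'   low-pass-filtered B rate, threshold 45 1/s).
#' * `reduction`: the f-I measurement/fit pipeline for the B population plus
#'   the membrane-potential optimization (scaled via `reduction_opts`).
#' * `bifurcation_suite`: one-parameter diagrams over `e`, every weight and
#'   `z`, plus the pathway-strength report.
#'
#' @param id experiment identifier.
#' @param seed master seed.
#' @param minutes duration override (minutes of simulated time).
#' @param out_dir optional output directory; events/statistics/manifest are
#'   written as CSV/JSON.
#' @param overrides named list of `network_spec` overrides
#'   (e.g. `list(clamp_eAB = 0.5)`).
#' @param reduction_opts options for the `reduction` protocol
#'   (`n_clones`, `T`, `current_step`).
#' @return a result bundle (list) with a `manifest` element sufficient to
#'   reproduce the run bit-identically.
#' @export
runExperiment <- function(id = c("bistable_clamp", "spontaneous", "evoked_P",
                                 "evoked_B", "evoked_A_hyper",
                                 "long_run_stats", "bp_depression",
                                 "pa_facilitation", "facilitation_only",
                                 "rate_noise", "reduction",
                                 "bifurcation_suite"),
                          seed = 1, minutes = NULL, out_dir = NULL,
                          overrides = list(),
                          reduction_opts = list(n_clones = 25, T = 5,
                                                current_step = 10)) {
  id <- match.arg(id)
  cfg <- list(id = id, seed = seed, minutes = minutes, overrides = overrides,
              reduction_opts = if (id == "reduction") reduction_opts else NULL)
  manifest <- list(id = id, seed = seed, minutes = minutes,
                   config_digest = .digest(cfg),
                   package = as.character(utils::packageVersion("swrnet")))

  spont_bundle <- function(preset, minutes_default, stimuli_fn = NULL,
                           det_preset = "default") {
    mins <- if (is.null(minutes)) minutes_default else minutes
    dur <- mins * 60000
    spec <- networkPreset(preset)
    for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
    net <- buildNetwork(spec, seed)
    stimuli <- if (is.null(stimuli_fn)) list() else stimuli_fn(dur)
    onsets <- if (length(stimuli)) stimuli[[1]]$onsets else NULL
    tr <- simulateNetwork(net, duration = dur, stimuli = stimuli)
    lfp <- lfpProxy(tr)
    ev <- detectSWREvents(lfp, preset = det_preset, evoked_onsets = onsets)
    stats <- if (nrow(ev) >= 4) eventStatistics(ev) else NULL
    list(manifest = manifest, trace = tr, lfp = lfp, events = ev,
         stats = stats)
  }

  res <- switch(id,
    bistable_clamp = {
      spec <- defaultNetworkSpec(clamp_eAB = 0.5)
      for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
      net <- buildNetwork(spec, seed)
      stim <- list(
        stimulusProtocol("P", 0.6, 300, 10, onsets = 1500),
        stimulusProtocol("P", 0.6, -300, 10, onsets = 3500))
      tr <- simulateNetwork(net, duration = 5000, stimuli = stim)
      win_non <- tr$t > 500 & tr$t < 1500
      win_swr <- tr$t > 2000 & tr$t < 3500
      list(manifest = manifest, trace = tr,
           nonswr_rates = colMeans(tr$rates[win_non, ]),
           swr_rates = colMeans(tr$rates[win_swr, ]),
           events = detectSWREvents(lfpProxy(tr)))
    },
    spontaneous = spont_bundle("default", 1),
    long_run_stats = spont_bundle("default", 10),
    bp_depression = spont_bundle("bp-depression", 1),
    pa_facilitation = spont_bundle("pa-facilitation", 1),
    facilitation_only = spont_bundle("facilitation-only", 1,
                                     det_preset = "facilitation-only"),
    evoked_P = spont_bundle("default", 1, function(dur)
      list(stimulusProtocol("P", 0.6, 300, 10, .periodic_pulses(dur),
                            jitter_max = 90))),
    evoked_B = spont_bundle("default", 1, function(dur)
      list(stimulusProtocol("B", 0.6, 600, 10, .periodic_pulses(dur),
                            jitter_max = 90))),
    evoked_A_hyper = spont_bundle("default", 1, function(dur)
      list(stimulusProtocol("A", 0.6, -500, 10, .periodic_pulses(dur),
                            jitter_max = 90))),
    rate_noise = {
      mins <- if (is.null(minutes)) 1 else minutes
      dur <- mins * 60
      params <- defaultRateParams()
      cfg_noise <- noiseConfigFromSpiking(defaultNetworkSpec())
      noise <- generateSynapticNoise(cfg_noise, dur, dt = 1e-4, seed = seed)
      tr <- simulateRate(params, init = c(0, 0, 12.5), duration = dur,
                         noise = noise, e0 = 1)
      b_lp <- .butter_filtfilt(tr$rates[, "B"], 1 / tr$dt_sample, "low", 10)
      ev <- detectSWREvents(b_lp, dt = tr$dt_sample * 1000, preset = "rate")
      stats <- if (nrow(ev) >= 4) eventStatistics(ev) else NULL
      list(manifest = manifest, trace = tr, events = ev, stats = stats)
    },
    reduction = {
      net <- buildNetwork(defaultNetworkSpec(), seed)
      cur <- seq(-100, 200, by = reduction_opts$current_step)
      lo <- measureFICurves(net, "non-SWR", "B", cur,
                            reduction_opts$n_clones, reduction_opts$T)
      hi <- measureFICurves(net, "SWR", "B", cur,
                            reduction_opts$n_clones, reduction_opts$T)
      fit <- fitSoftplus(assembleEmpiricalFI(lo, hi))
      list(manifest = manifest, curves = list(nonswr = lo, swr = hi),
           fit = fit)
    },
    bifurcation_suite = {
      params <- defaultRateParams()
      sweeps <- list(e = continueParameter(params, "e", c(0, 1)))
      for (post in POPS) for (pre in POPS) {
        nm <- paste0("W_", post, pre)
        upper <- if (nm == "W_PP") 4.5 else 15
        sweeps[[nm]] <- continueParameter(params, nm, c(0, upper))
      }
      sweeps$z <- continueParameter(params, "z", c(0, 1))
      list(manifest = manifest, sweeps = sweeps,
           pathways = pathwayStrengths(params))
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(res$events))
      write.csv(res$events, file.path(out_dir, "events.csv"),
                row.names = FALSE)
    if (!is.null(res$stats))
      jsonlite::write_json(res$stats[setdiff(names(res$stats), "expfit")],
                           file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}

#' Synthetic sharp-wave trace with known ground truth
#'
#' A sum of Gaussian bumps on a zero baseline plus white noise, used to
#' validate the event-detection pipeline against construction: amplitudes,
#' widths and event times are recorded as ground truth (the FWHM of a bump of
#' width `sigma` is `2 sigma sqrt(2 log 2)`).
#'
#' @param n_events number of bumps.
#' @param amp_mean,amp_sd bump amplitude distribution (pA).
#' @param width_sigma Gaussian bump width (ms).
#' @param iei_mean,iei_min gap distribution between bump centres (ms):
#'   `iei_min` plus an exponential with the remaining mean.
#' @param noise_sd white-noise SD (pA).
#' @param dt sample interval (ms).
#' @param seed RNG seed.
#' @param amp_iei_coef when non-NULL, amplitudes are
#'   `amp_mean + amp_iei_coef * (gap - mean gap)` (plants a correlation
#'   between amplitude and the preceding interval).
#' @param min_gap_sd error when two bump centres are closer than
#'   `min_gap_sd * width_sigma` (overlapping events beyond the limit).
#' @return an object of class `synthetic_sw`: `t`, `trace`, and a
#'   `ground_truth` data.frame (`time`, `amplitude`, `sigma`, `fwhm`).
#' @export
makeSyntheticSWTrace <- function(n_events, amp_mean = 70, amp_sd = 0,
                                 width_sigma = 40, iei_mean = 650,
                                 iei_min = 250, noise_sd = 0, dt = 1,
                                 seed = 1, amp_iei_coef = NULL,
                                 min_gap_sd = 3) {
  stopifnot(n_events >= 0, width_sigma > 0, iei_mean > iei_min)
  gt <- data.frame(time = numeric(0), amplitude = numeric(0),
                   sigma = numeric(0), fwhm = numeric(0))
  gaps <- amps <- numeric(0)
  if (n_events > 0) {
    gaps <- .with_rng(.stream_seed(seed, "fixture"),
                      iei_min + rexp(n_events, 1 / (iei_mean - iei_min)))
    if (any(gaps < min_gap_sd * width_sigma))
      stop("overlapping events beyond the configured limit")
    times <- 1000 + cumsum(gaps)
    amps <- if (!is.null(amp_iei_coef)) {
      amp_mean + amp_iei_coef * (gaps - mean(gaps))
    } else if (amp_sd > 0) {
      .with_rng(.stream_seed(seed, "fixture") + 1,
                rnorm(n_events, amp_mean, amp_sd))
    } else rep(amp_mean, n_events)
    gt <- data.frame(time = times, amplitude = amps, sigma = width_sigma,
                     fwhm = 2 * width_sigma * sqrt(2 * log(2)))
  }
  dur <- if (n_events > 0) max(gt$time) + 1000 else 5000
  t <- seq(0, dur, by = dt)
  trace <- numeric(length(t))
  for (i in seq_len(n_events))
    trace <- trace + gt$amplitude[i] *
      exp(-0.5 * ((t - gt$time[i]) / width_sigma)^2)
  if (noise_sd > 0)
    trace <- trace + .with_rng(.stream_seed(seed, "fixture") + 2,
                               rnorm(length(t), 0, noise_sd))
  structure(list(t = t, dt = dt, trace = trace, ground_truth = gt),
            class = "synthetic_sw")
}
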