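## LFP proxy, sharp-wave / ripple decomposition, SWR event detection and
## event statistics.

#' LFP proxy from the mean B->P synaptic current
#'
#' The local field potential in stratum pyramidale is approximated by the
#' synaptic input current from B (PV+ basket) cells onto pyramidal cells,
#' sign-reversed and averaged over all P cells.  The sharp-wave component is
#' the low-pass (<= 5 Hz) filtered proxy, the ripple component the band-pass
#' (90-180 Hz) filtered proxy; both use an order-2 Butterworth filter applied
#' forward-backward (zero phase, effective order 4).
#'
#' @param trace a `simulation_trace` (uses `curr_P[, "B"]`), or a numeric
#'   vector already containing the raw (sign-reversed) proxy.
#' @param dt sample interval in ms (taken from the trace if omitted).
#' @param sw_cutoff sharp-wave low-pass cutoff (Hz).
#' @param ripple_band ripple band (Hz).
#' @return an object of class `lfp_trace`: `t` (ms), `dt`, `raw`,
#'   `sharp_wave`, `ripple` (all pA).
#' @export
lfpProxy <- function(trace, dt = NULL, sw_cutoff = 5,
                     ripple_band = c(90, 180)) {
  if (inherits(trace, "simulation_trace")) {
    if (is.null(trace$curr_P)) stop("trace does not contain B->P currents")
    raw <- -trace$curr_P[, "B"]
    dt <- trace$dt_sample
    t <- trace$t
  } else {
    raw <- as.numeric(trace)
    if (is.null(dt)) stop("dt required for plain numeric input")
    t <- seq_along(raw) * dt - dt
  }
  fs <- 1000 / dt
  sw <- .butter_filtfilt(raw, fs, "low", sw_cutoff)
  rip <- .butter_filtfilt(raw, fs, "pass", ripple_band)
  structure(list(t = t, dt = dt, raw = raw, sharp_wave = sw, ripple = rip),
            class = "lfp_trace")
}

.butter_filtfilt <- function(x, fs, type, cutoff) {
  bf <- signal::butter(2, cutoff / (fs / 2), type = type)
  as.numeric(signal::filtfilt(bf, x))
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %d samples at %.2g ms; SW peak %.1f pA\n",
              length(x$raw), x$dt, max(x$sharp_wave)))
  invisible(x)
}

#' Detect sharp-wave events
#'
#' Finds local maxima of the sharp-wave trace above an amplitude threshold,
#' discards peaks closer than `min_separation` to a larger surviving peak
#' (largest first), and measures each event at half maximum.  The baseline is
#' the mean, across all events with at least 200 ms of history, of the
#' sharp-wave average in the window 200-100 ms before the peak; the half
#' maximum of an event is `(amplitude + baseline) / 2`.  Event start/end are
#' the half-maximum crossings flanking the peak; the inter-event interval
#' (IEI) runs from one event's end to the next event's start, so IEIs below
#' `min_separation` are possible.
#'
#' Detection presets: `"default"` 30 pA / 100 ms (spiking network),
#' `"facilitation-only"` 40 pA / 200 ms, `"rate"` 45 (spikes/s) / 100 ms on
#' the low-pass-filtered B rate of the rate model.
#'
#' @param x an `lfp_trace`, or a numeric sharp-wave/rate trace.
#' @param dt sample interval (ms) for numeric input.
#' @param amp_threshold minimal peak amplitude (pA, or spikes/s for the rate
#'   preset).
#' @param min_separation minimal separation between surviving peaks (ms).
#' @param preset named threshold preset; explicit arguments win.
#' @param evoked_onsets optional stimulation onset times (ms); an event is
#'   flagged `evoked` when an onset falls within `evoked_window` ms before
#'   its peak.
#' @param evoked_window association window for evoked flags (ms).
#' @return an `event_table` (a data.frame) with one row per event:
#'   `peak_time`, `amplitude`, `start`, `end`, `fwhm` (ms), `prev_iei`,
#'   `next_iei` (ms, NA at the borders), `evoked`.  Attributes: `baseline`,
#'   `duration`, `dt`.
#' @export
detectSWREvents <- function(x, dt = NULL, amp_threshold = NULL,
                            min_separation = NULL,
                            preset = c("default", "facilitation-only", "rate"),
                            evoked_onsets = NULL, evoked_window = 100) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    "default" = c(30, 100),
    "facilitation-only" = c(40, 200),
    "rate" = c(45, 100))
  if (is.null(amp_threshold)) amp_threshold <- defaults[1]
  if (is.null(min_separation)) min_separation <- defaults[2]
  stopifnot(amp_threshold > 0, min_separation > 0)
  if (inherits(x, "lfp_trace")) { sw <- x$sharp_wave; dt <- x$dt }
  else { sw <- as.numeric(x); if (is.null(dt)) stop("dt required") }
  n <- length(sw)

  peaks <- .local_maxima(sw)
  peaks <- peaks[sw[peaks] >= amp_threshold]
  peaks <- .enforce_separation(peaks, sw[peaks], min_separation / dt)

  empty <- data.frame(peak_time = numeric(0), amplitude = numeric(0),
                      start = numeric(0), end = numeric(0), fwhm = numeric(0),
                      prev_iei = numeric(0), next_iei = numeric(0),
                      evoked = logical(0))
  if (!length(peaks))
    return(structure(empty, class = c("event_table", "data.frame"),
                     baseline = NA_real_, duration = (n - 1) * dt, dt = dt))

  # baseline: mean over events of the SW mean in [peak-200, peak-100] ms
  pre_lo <- round(200 / dt); pre_hi <- round(100 / dt)
  with_hist <- peaks[peaks > pre_lo]
  if (!length(with_hist))
    stop("no detected peak has 200 ms of pre-peak history; baseline undefined")
  baseline <- mean(vapply(with_hist, function(p)
    mean(sw[(p - pre_lo):(p - pre_hi)]), 0))
  peaks <- with_hist  # first-event edge case: no history, no measurement

  rows <- lapply(peaks, function(p) {
    amp <- sw[p]
    half <- (amp + baseline) / 2
    below_l <- which(sw[1:(p - 1)] < half)
    below_r <- which(sw[(p + 1):n] < half)
    if (!length(below_l) || !length(below_r)) return(NULL)
    il <- max(below_l)          # last sample below half before the peak
    ir <- p + min(below_r)      # first sample below half after the peak
    # linear interpolation of the crossing between the flanking samples
    st <- (il - 1 + (half - sw[il]) / (sw[il + 1] - sw[il])) * dt
    en <- (ir - 2 + (half - sw[ir - 1]) / (sw[ir] - sw[ir - 1])) * dt
    data.frame(peak_time = (p - 1) * dt, amplitude = amp, start = st,
               end = en, fwhm = en - st)
  })
  ev <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(ev) || !nrow(ev))
    return(structure(empty, class = c("event_table", "data.frame"),
                     baseline = baseline, duration = (n - 1) * dt, dt = dt))
  ev <- ev[order(ev$peak_time), ]
  k <- nrow(ev)
  ev$prev_iei <- c(NA, ev$start[-1] - ev$end[-k])
  ev$next_iei <- c(ev$start[-1] - ev$end[-k], NA)
  ev$evoked <- FALSE
  if (!is.null(evoked_onsets) && length(evoked_onsets))
    ev$evoked <- vapply(seq_len(k), function(i)
      any(evoked_onsets >= ev$peak_time[i] - evoked_window &
          evoked_onsets <= ev$peak_time[i]), TRUE)
  rownames(ev) <- NULL
  structure(ev, class = c("event_table", "data.frame"), baseline = baseline,
            duration = (n - 1) * dt, dt = dt)
}

# strict local maxima; plateaus resolved to their first sample
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # indices where the signal was rising and next non-zero change is a fall
  rising <- which(d > 0)
  if (!length(rising)) return(integer(0))
  out <- integer(0)
  i <- 1
  while (i <= length(rising)) {
    p <- rising[i] + 1L  # candidate: first sample of a (possible) plateau
    j <- p
    while (j < n && x[j + 1] == x[j]) j <- j + 1L
    if (j == n || x[j + 1] < x[j]) out <- c(out, p)
    i <- i + 1L
    while (i <= length(rising) && rising[i] + 1L <= j) i <- i + 1L
  }
  out
}

# keep peaks greedily largest-first; drop any peak within min_sep samples of
# an already-kept larger peak
.enforce_separation <- function(idx, height, min_sep_samples) {
  if (length(idx) <= 1) return(idx)
  ord <- order(height, decreasing = TRUE)
  keep <- logical(length(idx))
  for (k in ord) {
    if (any(keep & abs(idx - idx[k]) < min_sep_samples)) next
    keep[k] <- TRUE
  }
  sort(idx[keep])
}

#' SWR-state mask from population rates
#'
#' A sample belongs to the SWR state when, simultaneously, the P rate is at
#' least `thresholds["P"]`, the B rate at least `thresholds["B"]`, and the A
#' rate at most `thresholds["A"]` (all spikes/s).  Defaults are half the
#' SWR-state rates for P and B and the 2 spikes/s criterion for A.
#'
#' @param rates matrix with columns `P`, `B`, `A` (or a `simulation_trace`).
#' @param thresholds named vector of the three thresholds.
#' @return logical vector.
#' @export
classifySWRState <- function(rates, thresholds = c(P = 20, B = 45, A = 2)) {
  if (inherits(rates, "simulation_trace")) rates <- rates$rates
  rates[, "P"] >= thresholds[["P"]] & rates[, "B"] >= thresholds[["B"]] &
    rates[, "A"] <= thresholds[["A"]]
}

#' Event statistics
#'
#' Summary statistics of an event table: IEI mean/SD (s), amplitude and FWHM
#' mean with standard errors, Pearson correlations (with two-sided p values)
#' between amplitude and previous/next IEI and between FWHM and previous IEI,
#' a nonlinear least-squares fit of `f(x) = a (1 - exp(-b x)) + c` to the
#' (previous IEI, amplitude) pairs, the smallest observed IEI, and the event
#' incidence.
#'
#' @param events an `event_table`.
#' @param restrict_to_evoked use only evoked events' amplitudes (paired with
#'   the surrounding intervals).
#' @param duration analysed duration (ms); defaults to the table attribute.
#'   The first 500 ms are treated as transient for the incidence.
#' @return an object of class `event_stats`.
#' @export
eventStatistics <- function(events, restrict_to_evoked = FALSE,
                            duration = attr(events, "duration")) {
  ev <- events
  if (restrict_to_evoked) ev <- ev[ev$evoked, ]
  n <- nrow(ev)
  iei <- ev$prev_iei[!is.na(ev$prev_iei)]
  pearson <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(list(r = NA_real_, p = NA_real_))
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
      stop("degenerate variance: correlation undefined")
    ct <- cor.test(x[ok], y[ok])
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  c_prev <- pearson(ev$amplitude, ev$prev_iei)
  c_next <- pearson(ev$amplitude, ev$next_iei)
  c_fwhm <- pearson(ev$fwhm, ev$prev_iei)

  expfit <- NULL
  ok <- !is.na(ev$prev_iei)
  if (sum(ok) >= 4) {
    df <- data.frame(x = ev$prev_iei[ok] / 1000, y = ev$amplitude[ok])
    start <- list(a = max(df$y) - min(df$y), b = 1 / mean(df$x), c = min(df$y))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * (1 - exp(-b * x)) + c, data = df,
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) expfit <- as.list(coef(fit))
  }
  analysed_s <- max((duration - 500) / 1000, 0)
  structure(list(
    n_events = n,
    iei_mean = mean(iei) / 1000, iei_sd = sd(iei) / 1000,
    amp_mean = mean(ev$amplitude),
    amp_sem = sd(ev$amplitude) / sqrt(max(n, 1)),
    fwhm_mean = mean(ev$fwhm),
    fwhm_sem = sd(ev$fwhm) / sqrt(max(n, 1)),
    r_amp_prev = c_prev$r, p_amp_prev = c_prev$p,
    r_amp_next = c_next$r, p_amp_next = c_next$p,
    r_fwhm_prev = c_fwhm$r, p_fwhm_prev = c_fwhm$p,
    expfit = expfit,
    min_observed_iei = if (length(iei)) min(iei) else NA_real_,
    incidence = if (analysed_s > 0) n / analysed_s else NA_real_),
    class = "event_stats")
}

#' @export
print.event_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<event_stats> %d events, incidence %.2f /s\n",
           "  IEI %.3f +/- %.3f s | amplitude %.2f +/- %.2f | ",
           "FWHM %.1f +/- %.1f ms\n",
           "  r(amp, prev IEI) = %.3f (p = %.2g); ",
           "r(amp, next IEI) = %.3f (p = %.2g)\n"),
    x$n_events, x$incidence, x$iei_mean, x$iei_sd, x$amp_mean, x$amp_sem,
    x$fwhm_mean, x$fwhm_sem, x$r_amp_prev, x$p_amp_prev, x$r_amp_next,
    x$p_amp_next))
  invisible(x)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram (Hann window, 50% overlap, zero-padding to
#' `nfft`).
#'
#' @param x numeric signal.
#' @param fs sampling frequency (Hz).
#' @param seg_len segment length in samples.
#' @param nfft FFT length (>= `seg_len`).
#' @return list with `freq` (Hz) and `power`.
#' @export
welchPSD <- function(x, fs, seg_len = min(length(x), 1024),
                     nfft = max(seg_len, 4096)) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len / 2))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  pw <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)] * w
    seg <- c(seg, numeric(nfft - seg_len))
    pw <- pw + Mod(fft(seg))^2
  }
  pw <- pw / (length(starts) * sum(w^2) * fs)
  half <- seq_len(floor(nfft / 2) + 1)
  list(freq = (half - 1) * fs / nfft, power = pw[half])
}

#' Ripple-band peak frequency
#'
#' Frequency of the maximum of the Welch-averaged power spectrum of the
#' ripple-band trace, restricted to the ripple band.
#'
#' @param x numeric ripple-band trace, a list of such traces (e.g. per-event
#'   segments, whose spectra are averaged), or an `lfp_trace`.
#' @param fs sampling frequency (Hz; taken from an `lfp_trace`).
#' @param band frequency band searched (Hz).
#' @param seg_len Welch segment length in samples (default 128 ms worth).
#' @return peak frequency (Hz).
#' @export
ripplePeakFrequency <- function(x, fs = NULL, band = c(90, 180),
                                seg_len = NULL) {
  if (inherits(x, "lfp_trace")) { fs <- 1000 / x$dt; x <- list(x$ripple) }
  if (!is.list(x)) x <- list(x)
  if (is.null(fs)) stop("fs required")
  if (is.null(seg_len)) seg_len <- round(fs * 0.128)
  tot <- sum(lengths(x))
  if (tot < fs) stop("need at least 1 s of signal")
  if (all(vapply(x, function(v) all(v == 0), TRUE)))
    stop("all-zero trace: ripple peak undefined")
  nfft <- 2^ceiling(log2(max(seg_len, 4096)))
  acc <- NULL
  for (seg in x) {
    if (length(seg) < 8) next
    p <- welchPSD(seg, fs, seg_len = min(seg_len, length(seg)), nfft = nfft)
    if (is.null(acc)) acc <- p else acc$power <- acc$power + p$power
  }
  sel <- acc$freq >= band[1] & acc$freq <= band[2]
  acc$freq[sel][which.max(acc$power[sel])]
}
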