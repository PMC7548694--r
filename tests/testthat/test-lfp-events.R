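test_that("filter components respond correctly to degenerate inputs", {
  z <- lfpProxy(rep(0, 4000), dt = 1)
  expect_true(all(abs(z$sharp_wave) < 1e-9))
  expect_true(all(abs(z$ripple) < 1e-9))
  # constant offset: DC passes the low-pass, vanishes in the ripple band
  cst <- lfpProxy(rep(25, 4000), dt = 1)
  mid <- 1000:3000
  expect_lt(max(abs(cst$sharp_wave[mid] - 25)), 0.01)
  expect_lt(max(abs(cst$ripple[mid])), 0.01)
})

test_that("zero-phase filtering leaves peak times invariant to time reversal", {
  x <- makeSyntheticSWTrace(10, seed = 3, noise_sd = 1)$trace
  f <- lfpProxy(x, dt = 1)$sharp_wave
  fr <- rev(lfpProxy(rev(x), dt = 1)$sharp_wave)
  expect_equal(which.max(f), which.max(fr))
  # interior samples agree; the filtfilt edge initialization is not exactly
  # time-symmetric, hence the margin
  mid <- 200:(length(f) - 200)
  expect_equal(f[mid], fr[mid], tolerance = 1e-6)
})

test_that("Gaussian bumps are measured at their closed-form geometry", {
  # two bumps, 70 pA, sigma = 40 ms, centred 1 s apart on a zero baseline
  t <- 0:4000
  sw <- 70 * exp(-0.5 * ((t - 1500) / 40)^2) +
        70 * exp(-0.5 * ((t - 2500) / 40)^2)
  ev <- detectSWREvents(sw, dt = 1)
  expect_equal(nrow(ev), 2)
  fwhm_true <- 2 * 40 * sqrt(2 * log(2))
  expect_equal(ev$fwhm, rep(fwhm_true, 2), tolerance = 0.02)
  expect_equal(ev$amplitude, c(70, 70), tolerance = 0.001)
  # IEI runs between the half-max crossings of consecutive events
  expect_equal(ev$prev_iei[2], 1000 - fwhm_true, tolerance = 0.02)
  expect_equal(ev$prev_iei[2], ev$next_iei[1])
  # flat trace below threshold: no events
  expect_equal(nrow(detectSWREvents(rep(10, 3000), dt = 1)), 0)
})

test_that("event count is invariant under a constant baseline offset", {
  sw <- makeSyntheticSWTrace(12, seed = 4, noise_sd = 0.5)
  e0 <- detectSWREvents(sw$trace, dt = 1)
  e1 <- detectSWREvents(sw$trace + 20, dt = 1)
  expect_equal(nrow(e1), nrow(e0))
  # half-max measurement is baseline-corrected, so widths agree
  expect_equal(e1$fwhm, e0$fwhm, tolerance = 0.02)
})

test_that("detection has unit recall and accurate amplitudes on clean bumps", {
  sw <- makeSyntheticSWTrace(50, amp_mean = 70, width_sigma = 40,
                             iei_mean = 650, noise_sd = 2, seed = 5)
  # detect on a low-passed trace, as the pipeline does (20 Hz preserves the
  # 40 ms bumps while suppressing the white noise)
  lp <- lfpProxy(sw$trace, dt = 1, sw_cutoff = 20)
  ev <- detectSWREvents(lp)
  gt <- sw$ground_truth
  matched <- vapply(gt$time, function(tt) any(abs(ev$peak_time - tt) < 25), TRUE)
  expect_true(all(matched))                       # recall = 1
  expect_equal(nrow(ev), nrow(gt))                # no spurious events
  idx <- vapply(gt$time, function(tt) which.min(abs(ev$peak_time - tt)), 1L)
  expect_lt(max(abs(ev$amplitude[idx] - gt$amplitude) / gt$amplitude), 0.03)
  expect_lt(max(abs(ev$fwhm[idx] - gt$fwhm) / gt$fwhm), 0.03)
})

test_that("minimum-separation pruning keeps the larger peak", {
  t <- 0:1000
  sw <- 80 * exp(-0.5 * ((t - 400) / 20)^2) + 50 * exp(-0.5 * ((t - 460) / 20)^2)
  ev <- detectSWREvents(sw, dt = 1, min_separation = 100)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_time, 400, tolerance = 2)
})

test_that("SWR-state classification requires all three conditions", {
  r <- rbind(c(2, 1, 12), c(43, 90, 1), c(43, 90, 12))
  colnames(r) <- c("P", "B", "A")
  expect_equal(classifySWRState(r), c(FALSE, TRUE, FALSE))
})

test_that("event statistics reproduce textbook correlations and fail safely", {
  ev <- data.frame(peak_time = c(1000, 2000, 3000, 4000),
                   amplitude = c(50, 2 * 30, 2 * 60, 2 * 45),
                   start = c(950, 1950, 2950, 3950),
                   end = c(1050, 2050, 3050, 4050),
                   fwhm = c(100, 95, 110, 90),
                   prev_iei = c(NA, 30, 60, 45),
                   next_iei = c(30, 60, 45, NA), evoked = FALSE)
  attr(ev, "duration") <- 5000
  st <- eventStatistics(ev)
  expect_equal(st$r_amp_prev, 1)      # amplitudes exactly linear in prev IEI
  expect_lt(st$p_amp_prev, 1e-6)
  expect_equal(st$min_observed_iei, 30)
  expect_equal(st$incidence, 4 / 4.5)
  ev$amplitude <- rep(60, 4)
  expect_error(eventStatistics(ev), "degenerate")
})

test_that("planted IEI-amplitude correlation is recovered", {
  sw <- makeSyntheticSWTrace(60, amp_mean = 70, amp_iei_coef = 0.05,
                             noise_sd = 1, seed = 6)
  ev <- detectSWREvents(sw$trace, dt = 1)
  st <- eventStatistics(ev)
  expect_gt(st$r_amp_prev, 0.9)
  expect_lt(abs(st$r_amp_next), 0.35)
  # exponential fit of amplitude vs previous IEI converges
  expect_false(is.null(st$expfit))
})

test_that("spectral peak estimation finds known frequencies", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  expect_equal(ripplePeakFrequency(sin(2 * pi * 135 * t), fs = fs), 135,
               tolerance = 0.01)
  set.seed(7)
  noisy <- sin(2 * pi * 120 * t) + rnorm(length(t), 0, sqrt(1 / 20))
  expect_equal(ripplePeakFrequency(noisy, fs = fs), 120, tolerance = 1 / 120)
  expect_error(ripplePeakFrequency(rep(0, 2000), fs = fs), "undefined")
  expect_error(ripplePeakFrequency(sin(2 * pi * 135 * t[1:100]), fs = fs),
               "1 s")
})

test_that("synthetic fixture generator honours its contracts", {
  s0 <- makeSyntheticSWTrace(0, seed = 1)
  expect_equal(nrow(s0$ground_truth), 0)
  expect_true(all(s0$trace == 0))
  expect_error(makeSyntheticSWTrace(30, width_sigma = 40, iei_mean = 200,
                                    iei_min = 50, seed = 1),
               "overlapping")
  # ground truth consistent with the trace construction
  s1 <- makeSyntheticSWTrace(5, seed = 2)
  peak_vals <- s1$trace[match(round(s1$ground_truth$time), s1$t)]
  expect_equal(peak_vals, s1$ground_truth$amplitude, tolerance = 0.02)
})
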