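test_that("softplus activation has the right midpoint and asymptote", {
  expect_equal(softplusActivation(-131.66, 0.47, 131.66), log(2))
  # linear regime: k (x + t) = 30
  x <- 30 / 0.41 - 131.96
  expect_equal(softplusActivation(x, 0.41, 131.96), 30, tolerance = 1e-12)
  # numerically stable far in both tails
  expect_equal(softplusActivation(1e4, 0.5, 0), 5e3)
  expect_equal(softplusActivation(-1e4, 0.5, 0), 0)
})

test_that("the A population's self-consistent rate is ~12.5 spikes/s", {
  # 1-D root of A = f_A(-W_AA A) with the reference parameters
  h <- function(a) softplusActivation(-8.40 * a, 0.48, 131.09) - a
  a_star <- uniroot(h, c(0, 100), tol = 1e-10)$root
  expect_equal(a_star, 12.5, tolerance = 0.01)
})

test_that("the weight mapping reproduces the reference weights exactly", {
  W <- weightsFromSpiking(defaultNetworkSpec(),
                          V = c(P = -52.5, B = -54.0, A = -52.5))
  ref <- rbind(P = c(1.72, 1.24, 12.60),
               B = c(8.86, 3.24, 13.44),
               A = c(1.72, 5.67, 8.40))
  colnames(ref) <- c("P", "B", "A")
  expect_equal(round(W, 2), ref)
  # zero conductance gives zero weight
  spec <- defaultNetworkSpec()
  spec$synapses$PB$g_unit <- 0
  expect_equal(weightsFromSpiking(spec)["B", "P"], 0)
  # membrane potential on the wrong side of the reversal potential
  expect_error(weightsFromSpiking(defaultNetworkSpec(),
                                  V = c(P = -75, B = -54, A = -52.5)),
               "negative weight")
})

test_that("the decoupled rate model converges to f_I(0)", {
  p <- defaultRateParams()
  p$W[] <- 0
  tr <- simulateRate(p, init = c(5, 5, 5), duration = 0.5, e0 = 0.2)
  fin <- nrow(tr$rates)
  expect_equal(unname(tr$rates[fin, ]),
               unname(softplusActivation(0, p$k, p$t)), tolerance = 1e-6)
  # e settles at its B-dependent steady state 1 / (1 + eta_d tau_d B)
  expect_equal(tr$e[fin],
               unname(1 / (1 + p$eta_d * p$tau_d * tr$rates[fin, "B"])),
               tolerance = 1e-3)
})

test_that("fixed points are invariant under simulation", {
  p <- defaultRateParams()
  fp <- steadyStates(p, e = 0.5)
  stable <- fp[fp$stable, ]
  for (i in seq_len(nrow(stable))) {
    tr <- simulateRate(p, init = as.numeric(stable[i, 1:3]), duration = 10,
                       e_clamp = 0.5, record_every = 1000L)
    drift <- max(abs(tr$rates[nrow(tr$rates), ] - as.numeric(stable[i, 1:3])))
    expect_lt(drift, 1e-6)
  }
})

test_that("the depression variable stays inside [0, 1] under any input", {
  p <- defaultRateParams()
  stim <- list(list(target = "B", amplitude = 500, onset = 0.05,
                    duration = 0.3),
               list(target = "B", amplitude = -800, onset = 0.5,
                    duration = 0.3))
  tr <- simulateRate(p, init = c(0, 0, 12.5), duration = 1, e0 = 0.99,
                     stimuli = stim)
  expect_true(all(tr$e >= 0 & tr$e <= 1))
})

test_that("generated shot noise obeys Campbell's theorem", {
  cfg <- structure(
    data.frame(post = "P", pre = "P", rate = 300, amplitude = 2, tau = 0.004),
    class = c("noise_config", "data.frame"), divisor = 1)
  x <- generateSynapticNoise(cfg, duration = 100, dt = 1e-4, seed = 11)
  m_th <- 300 * 2 * 0.004        # rate * a * tau
  v_th <- 300 * 4 * 0.004 / 2    # rate * a^2 * tau / 2
  # effective sample count for the autocorrelated shot process
  n_eff <- 100 / (2 * 0.004)
  expect_lt(abs(attr(x, "pair_mean")[1] - m_th), 3 * sqrt(v_th / n_eff))
  expect_lt(abs(attr(x, "pair_var")[1] - v_th), 3 * v_th * sqrt(2 / n_eff))
  # delivered currents are zero-mean and scaled by the divisor
  expect_equal(mean(x[1, ]), 0, tolerance = 1e-12)
  expect_equal(rowSums(abs(x))[2:3], c(0, 0), ignore_attr = TRUE)
})

test_that("silent presynaptic populations generate no noise", {
  cfg <- noiseConfigFromSpiking(defaultNetworkSpec(),
                                rates_nonswr = c(P = 0, B = 0, A = 0))
  x <- generateSynapticNoise(cfg, duration = 1, dt = 1e-3, seed = 1)
  expect_true(all(x == 0))
})

test_that("the noisy rate model produces events with the right structure", {
  params <- defaultRateParams()
  cfg <- noiseConfigFromSpiking(defaultNetworkSpec())
  noise <- generateSynapticNoise(cfg, 60, dt = 1e-4, seed = 2)
  tr <- simulateRate(params, init = c(0, 0, 12.5), duration = 60,
                     noise = noise)
  b_lp <- swrnet:::.butter_filtfilt(tr$rates[, "B"], 1 / tr$dt_sample,
                                    "low", 10)
  ev <- detectSWREvents(b_lp, dt = tr$dt_sample * 1000, preset = "rate")
  expect_gt(nrow(ev), 20)        # spontaneous events at O(1)/s
  st <- eventStatistics(ev)
  expect_gt(st$r_amp_prev, 0.25) # amplitude correlates with the previous IEI
  expect_lt(abs(st$r_amp_next), 0.3)
  expect_true(all(tr$e >= 0 & tr$e <= 1))
})
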