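test_that("clone neurons never feed back into the network", {
  net <- small_net(4, scale = 0.1)
  base <- simulateNetwork(net, 800, record_spikes = list(P = "all", B = "all",
                                                         A = "all"))
  # clones of the first two B cells, fully connected copies of their inputs
  nB <- net$n[["B"]]
  adj <- lapply(0:8, function(t) {
    n_pre <- net$n[[c("P", "B", "A")[t %/% 3 + 1]]]
    list(offsets = integer(n_pre + 1), targets = integer(0))
  })
  # wire clone 0 to receive from every P cell (arbitrary read-only wiring)
  nP <- net$n[["P"]]
  adj[[2]] <- list(offsets = 0:nP, targets = rep(0L, nP)) # type P->B
  with_cl <- simulateNetwork(net, 800,
    record_spikes = list(P = "all", B = "all", A = "all"),
    clones = list(pop = c(1L, 1L), Iext = c(0, 50), adj = adj))
  expect_identical(base$spikes, with_cl$spikes)
  expect_identical(base$curr_P, with_cl$curr_P)
})

test_that("isolated clones reproduce the closed-form LIF f-I curve", {
  net <- buildNetwork(isolated_spec(I_BG = 200), seed = 1)
  adj <- lapply(0:8, function(t) {
    n_pre <- net$n[[c("P", "B", "A")[t %/% 3 + 1]]]
    list(offsets = integer(n_pre + 1), targets = integer(0))
  })
  iext <- c(-150, -100, 0, 100, 200)   # totals 50...400 pA
  tr <- simulateNetwork(net, 10500,
    clones = list(pop = rep(0L, length(iext)), Iext = iext, adj = adj),
    transient_ms = 500)
  expected <- vapply(iext + 200, lif_rate, 0)
  expect_equal(tr$clone_rate[expected == 0], c(0, 0), ignore_attr = TRUE)
  nz <- expected > 0
  expect_lt(max(abs(tr$clone_rate[nz] - expected[nz]) / expected[nz]), 0.01)
  # measured mean input equals the injected total current
  expect_equal(tr$clone_curr_mean, iext + 200, tolerance = 0.001,
               ignore_attr = TRUE)
})

test_that("empirical f-I assembly splices at the active-state threshold", {
  mk <- function(state, pop, rate_fun, input_mean, input_sd) {
    grid <- seq(-100, 200, by = 10)
    structure(data.frame(current_ext = grid, input_mean = grid,
                         rate = rate_fun(grid)),
              class = c("fi_curve", "data.frame"), state = state,
              population = pop, input_mean0 = input_mean,
              input_sd0 = input_sd, n_clones = 1, T = 1)
  }
  lo <- mk("non-SWR", "B", function(x) rep(0, length(x)), 0, 10)
  hi <- mk("SWR", "B", function(x) pmax(x, 0) / 10, 60, 10)
  emp <- assembleEmpiricalFI(lo, hi)
  expect_equal(attr(emp, "splice"), 50)
  expect_true(all(emp$rate[emp$input < 50] == 0))
  expect_equal(emp$rate[emp$input >= 50], pmax(emp$input[emp$input >= 50], 0) / 10)
  # identical curves: splice is a no-op
  lo2 <- mk("non-SWR", "B", function(x) x^0, 50, 10)
  hi2 <- mk("SWR", "B", function(x) x^0, 50, 10)
  emp2 <- assembleEmpiricalFI(lo2, hi2)
  expect_true(all(emp2$rate == 1))
})

test_that("softplus fitting is self-consistent and flags degenerate data", {
  grid <- seq(-100, 200, by = 5)
  curve <- data.frame(input = grid,
                      rate = softplusActivation(grid, 0.5, -70))
  fit <- fitSoftplus(curve)
  expect_equal(fit$k, 0.5, tolerance = 1e-4)
  expect_equal(fit$s, -70, tolerance = 1e-4)
  expect_equal(fit$t, fit$s + 200)
  flat <- data.frame(input = grid, rate = 0)
  expect_true(fitSoftplus(flat)$degenerate)
  # subsampling the grid by two barely moves the parameters
  fit2 <- fitSoftplus(curve[seq(1, nrow(curve), by = 2), ])
  expect_lt(abs(fit2$k - fit$k) / fit$k, 0.02)
})

test_that("membrane-potential optimization handles edge cases", {
  act <- list(k = c(0.47, 0.41, 0.48), t = c(131.66, 131.96, 131.09))
  spec <- defaultNetworkSpec()
  res <- optimizeMembranePotentials(spec, act, V_grid = c(-54, -52.5))
  # a grid point whose achieved rates are the targets has objective 0
  res2 <- optimizeMembranePotentials(spec, act, targets = res$achieved,
                                     V_grid = c(-54, -52.5))
  expect_equal(res2$V, res$V)
  expect_lt(res2$objective, 1e-10)
  # impossible biological bounds leave no admissible combination
  bad <- list(nonswr = list(P = c(-Inf, 5), B = c(-Inf, 5), A = c(100, Inf)),
              swr = list(P = c(8, Inf), B = c(30, Inf), A = c(-Inf, 5)))
  expect_error(
    optimizeMembranePotentials(spec, act, V_grid = c(-54, -52.5),
                               bio_ranges = bad),
    "no admissible")
})
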