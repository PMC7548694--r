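test_that("specification invariants are enforced", {
  expect_error(populationSpec("X", 10, E_rev_out = 0, tau_syn_out = 2))
  expect_error(synapseSpec("P", "B", p_conn = 1.2, g_unit = 1))
  expect_error(synapseSpec("P", "B", p_conn = 0.5, g_unit = -1))
  expect_error(depression(eta_D = 1.5) |> synapseSpec("B", "A", 0.2, 8,
                                                      plasticity = _))
  # nine directed pairs exactly once
  spec <- defaultNetworkSpec()
  expect_error(networkSpec(spec$populations, spec$synapses[-1]))
  dup <- spec$synapses
  dup[[1]] <- dup[[2]]
  expect_error(networkSpec(spec$populations, dup))
  expect_error(networkSpec(spec$populations, spec$synapses, clamp_eAB = 1.5))
})

test_that("default specification carries the reference parameter tables", {
  spec <- defaultNetworkSpec()
  n <- vapply(spec$populations, `[[`, 0L, "n_cells")
  expect_equal(unname(n), c(8200L, 135L, 50L))
  expect_equal(spec$synapses$BA$g_unit, 8)
  expect_equal(spec$synapses$BA$plasticity$eta_D, 0.18)
  expect_equal(spec$synapses$BA$plasticity$tau_D, 250)
  expect_equal(spec$synapses$AP$p_conn, 0.6)
  expect_equal(spec$I_BG, 200)
  fac <- networkPreset("facilitation-only")
  expect_equal(fac$synapses$BA$g_unit, 4.5)
  expect_equal(fac$synapses$AB$g_unit, 5.5)
  expect_equal(fac$synapses$PA$plasticity$eta_F, 0.32)
  expect_equal(fac$clamp_eAB, 0.5)
})

test_that("network specs survive a JSON round trip", {
  spec <- networkPreset("pa-facilitation")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  writeNetworkSpec(spec, path)
  back <- readNetworkSpec(path)
  expect_equal(back, spec)
})

test_that("connectivity sampling matches its Bernoulli model", {
  # zero probability: empty adjacency
  net0 <- buildNetwork(isolated_spec(50, 20, 10), seed = 1)
  expect_true(all(net0$counts == 0))
  # realized B->A count within 4 binomial SDs of N_B N_A p = 1350
  net <- buildNetwork(defaultNetworkSpec(), seed = 7)
  exp_ba <- 135 * 50 * 0.2
  sd_ba <- sqrt(135 * 50 * 0.2 * 0.8)
  expect_lt(abs(net$counts[["BA"]] - exp_ba), 4 * sd_ba)
  # all nine types within 4 SDs
  for (s in defaultNetworkSpec()$synapses) {
    n_pre <- net$n[[s$pre]]; n_post <- net$n[[s$post]]
    m <- n_pre * n_post * s$p_conn - (s$pre == s$post) * n_pre * s$p_conn
    sdv <- sqrt(max(n_pre * n_post * s$p_conn * (1 - s$p_conn), 1))
    expect_lt(abs(net$counts[[paste0(s$pre, s$post)]] - m), 4 * sdv)
  }
  # no self-connections
  a <- net$adjacency$PP
  pre <- rep(seq_len(8200) - 1L, diff(a$offsets))
  expect_false(any(pre == a$targets))
})

test_that("connectivity is a deterministic function of the seed", {
  n1 <- buildNetwork(defaultNetworkSpec(scale = 0.1), seed = 1)
  n2 <- buildNetwork(defaultNetworkSpec(scale = 0.1), seed = 1)
  n3 <- buildNetwork(defaultNetworkSpec(scale = 0.1), seed = 2)
  expect_identical(n1$adjacency, n2$adjacency)
  expect_false(identical(n1$adjacency, n3$adjacency))
})

test_that("baseline facilitation level follows its stationary formula", {
  expect_equal(zNonSWR(2, 0.15, 250, 1), 0.075 / 1.075, tolerance = 1e-12)
})
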