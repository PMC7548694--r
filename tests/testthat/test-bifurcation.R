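test_that("fixed-point structure changes between e = 0.4 and e = 0.5", {
  p <- defaultRateParams()
  fp4 <- steadyStates(p, e = 0.4)
  expect_equal(nrow(fp4), 1)
  expect_equal(as.numeric(fp4[1, 1:3]), c(0, 0, 12.5), tolerance = 0.01)
  expect_true(fp4$stable)
  fp5 <- steadyStates(p, e = 0.5)
  expect_equal(nrow(fp5), 3)
  expect_equal(fp5$stable, c(TRUE, FALSE, TRUE))   # non-SWR, threshold, SWR
  expect_true(all(fp5$residual < 1e-8))
  swr <- fp5[3, ]
  expect_equal(as.numeric(swr[1, 1:3]), c(43.9, 91.7, 0), tolerance = 0.01)
})

test_that("the decoupled system has a unique stable fixed point at f_I(0)", {
  p <- defaultRateParams()
  p$W[] <- 0
  fp <- steadyStates(p, e = 0.5)
  expect_equal(nrow(fp), 1)
  expect_true(fp$stable)
  expect_equal(as.numeric(fp[1, 1:3]),
               unname(softplusActivation(0, p$k, p$t)), tolerance = 1e-6)
})

test_that("slow nullclines evaluate to their closed forms", {
  p <- defaultRateParams()
  nc <- nullclines(p, "Be")
  expect_equal(nc$e_nullcline(0), 1)
  expect_equal(nc$e_nullcline(91.9), 1 / (1 + 0.18 * 0.25 * 91.9))
  expect_equal(nc$z_nullcline(0), 0)
  # rate-plane nullclines vanish at the fixed points
  pb <- nullclines(p, "PB", e = 0.5, grid = seq(0, 100, length.out = 21))
  expect_true(is.matrix(pb$rhs1) && all(dim(pb$rhs1) == c(21, 21)))
  # at the origin-like fixed point (P = B ~ 0) both RHS are ~0
  expect_lt(abs(pb$rhs1[1, 1]), 0.01)
  expect_lt(abs(pb$rhs2[1, 1]), 0.01)
})

test_that("continuation detects the depression fold and matches dense counts", {
  p <- defaultRateParams()
  bd <- continueParameter(p, "e", c(0.3, 0.6), n_grid = 61)
  expect_equal(length(bd$folds), 1)
  # independent dense-grid oracle around the fold
  lo <- bd$folds - 0.005; hi <- bd$folds + 0.005
  expect_equal(nrow(steadyStates(p, e = lo)), 1)
  expect_equal(nrow(steadyStates(p, e = hi)), 3)
  # branch points satisfy the steady-state residual bound
  expect_true(all(bd$points$residual < 1e-8))
})

test_that("fast-slow geometry: the e-nullcline sits between the branches", {
  p <- defaultRateParams()
  e_test <- 0.42
  fp <- steadyStates(p, e = e_test)
  expect_equal(nrow(fp), 3)
  b_sorted <- sort(fp$B)
  b_null <- (1 - e_test) / (e_test * p$eta_d * p$tau_d)
  expect_gt(b_null, b_sorted[1])   # above the non-SWR branch
  expect_lt(b_null, b_sorted[2])   # below the threshold branch
})

test_that("recurrent-excitation sweep reports blow-up, not a fold", {
  p <- defaultRateParams()
  bd <- continueParameter(p, "W_PP", c(3, 4.2), n_grid = 61)
  expect_false(is.na(bd$blowup))
  expect_gt(bd$blowup, 3.5)
  # beyond the truncation, the tracked high-activity branch exceeds the cap
  above <- bd$points[bd$points$param > bd$blowup + 0.01, ]
  expect_true(all(above$P <= bd$cap))
})

test_that("pathway strengths follow the linear approximation formulas", {
  p <- defaultRateParams()
  pw <- pathwayStrengths(p)
  expect_equal(pw$direct$strength[pw$direct$pathway == "P->A"],
               0.48 * 1.72 / (1 + 0.48 * 8.40), tolerance = 1e-12)
  r1 <- pw$requirements[1, ]
  expect_equal(r1$lhs, 1.72 * (1 + 0.41 * 3.24), tolerance = 1e-12)
  expect_equal(r1$rhs, 0.41 * 8.86 * 5.67, tolerance = 1e-12)
  expect_true(all(pw$requirements$satisfied))
  # indirect strengths are products of their constituents
  d <- setNames(pw$direct$strength, pw$direct$pathway)
  i <- setNames(pw$indirect$strength, pw$indirect$pathway)
  expect_equal(i[["P->B->A"]], d[["P->B"]] * d[["B->A"]])
  expect_equal(i[["B->A->P"]], d[["B->A"]] * d[["A->P"]])
  # removing P->B collapses the disynaptic inhibition of A
  p0 <- p; p0$W["B", "P"] <- 0
  pw0 <- pathwayStrengths(p0)
  expect_false(pw0$requirements$satisfied[1])
  expect_equal(pw0$indirect$strength[pw0$indirect$pathway == "P->B->A"], 0)
})

test_that("the 2-D bistable mask agrees with pointwise classification", {
  p <- defaultRateParams()
  reg <- bistableRegion2d(p, c("W_AP", "W_AB"), list(c(0, 4), c(3, 9)),
                          resolution = 9, e = 0.5)
  # default parameter point lies inside the bistable region
  i <- which.min(abs(reg$x - 1.72)); j <- which.min(abs(reg$y - 5.67))
  expect_true(reg$bistable[i, j])
  # spot-check four grid points against direct fixed-point counts
  for (idx in list(c(1, 1), c(9, 9), c(5, 5), c(2, 8))) {
    q <- p; q$W["A", "P"] <- reg$x[idx[1]]; q$W["A", "B"] <- reg$y[idx[2]]
    n_direct <- nrow(steadyStates(q, e = 0.5))
    expect_equal(reg$n_fp[idx[1], idx[2]], n_direct)
  }
  # zero mutual inhibition between the interneuron classes: monostable
  q <- p; q$W["A", "B"] <- 0; q$W["B", "A"] <- 0
  expect_equal(nrow(steadyStates(q, e = 0.5)), 1)
})
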