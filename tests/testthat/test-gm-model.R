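test_that("reaction terms reproduce the kinetic equations", {
  p <- tableParams()
  # A = 0, H = 1: only basal activator production and inhibitor balance
  rt <- reactionTerms(p, A = 0, H = 1)
  expect_equal(rt$dA, 0.2 * 0.003^2)
  expect_equal(rt$dH, 1e-4 - 0.6)
  # without basal terms every activator source vanishes at A = 0
  p0 <- gmParameters(rho_A = 1e-300, rho_H = 1e-300)
  rt0 <- reactionTerms(p0, A = 0, H = 1)
  expect_equal(rt0$dA, 0, tolerance = 1e-12)
  expect_equal(rt0$dH, -0.6)
  expect_error(reactionTerms(p, 1, 0), "positive")
  expect_error(reactionTerms(p, 1, -2), "positive")
})

test_that("steady state balances the kinetics and matches the closed form", {
  p <- tableParams()
  ss <- steadyState(p)
  rt <- reactionTerms(p, ss@A, ss@H)
  expect_lt(abs(rt$dA), 1e-10)
  expect_lt(abs(rt$dH), 1e-10)
  # closed form when the basal terms are (numerically) absent
  pz <- gmParameters(rho_A = 1e-300, rho_H = 1e-300)
  ssz <- steadyState(pz)
  expect_equal(ssz@A, 0.2 * 0.6 / (0.2 * 0.21), tolerance = 1e-9)
  expect_equal(ssz@H, 0.2 * ssz@A^2 / 0.6, tolerance = 1e-9)
  # full parameterization stays within ~1% of the closed form
  expect_equal(ss@A, ssz@A, tolerance = 0.01)
  expect_equal(ss@H, ssz@H, tolerance = 0.01)
  # a decay-free activator has no finite balance; positivity is enforced at
  # construction
  expect_error(gmParameters(mu_A = 0), "positive")
  expect_error(gmParameters(D_H = -1), "positive")
})

test_that("steady-state residual stays below tolerance across random
           parameter sets", {
  set.seed(42)
  for (i in 1:25) {
    p <- randomParams()
    ss <- steadyState(p)
    rt <- reactionTerms(p, ss@A, ss@H)
    expect_lt(abs(rt$dA), 1e-10)
    expect_lt(abs(rt$dH), 1e-10)
  }
})

test_that("analytic linearization agrees with finite differences", {
  set.seed(7)
  for (i in 1:100) {
    p <- randomParams()
    ss <- steadyState(p)
    lin <- linearize(p, ss)
    fd <- fdLinearize(p, ss)
    expect_equal(lin@f_A, fd[["f_A"]], tolerance = 1e-6)
    expect_equal(lin@f_H, fd[["f_H"]], tolerance = 1e-6)
    expect_equal(lin@g_A, fd[["g_A"]], tolerance = 1e-6)
    expect_equal(lin@g_H, fd[["g_H"]], tolerance = 1e-6)
    # the inhibitor equation is linear in H, so g_H is exactly -mu_H
    expect_equal(lin@g_H, -p@mu_H)
    expect_equal(lin@trace, lin@f_A + lin@g_H)
  }
})

test_that("activator-inhibitor sign structure holds at the base
           parameterization", {
  lin <- linearize(tableParams())
  expect_gt(lin@f_A, 0)
  expect_lt(lin@f_H, 0)
  expect_gt(lin@g_A, 0)
  expect_lt(lin@trace, 0)
  expect_gt(lin@det, 0)
})

test_that("Turing criteria hold at the base parameters and the band matches
           the dispersion-rate oracle", {
  p <- tableParams()
  tr <- turingCheck(p)
  expect_true(tr@stableWithoutDiffusion)
  expect_true(tr@diffusionDrivenInstability)
  expect_true(tr@satisfied)
  band <- dispersionBandOracle(p)
  expect_equal(tr@k2Minus, band[1], tolerance = 1e-6)
  expect_equal(tr@k2Plus, band[2], tolerance = 1e-6)
  expect_lt(tr@k2Minus, tr@k2Plus)
  # equal diffusivities with a stable reaction part cannot destabilize
  peq <- scaleParameter(p, "D_H", p@D_A / p@D_H)
  expect_false(turingCheck(peq)@satisfied)
  expect_true(is.na(turingCheck(peq)@k2Minus))
})

test_that("dispersion rate is positive exactly inside the unstable band", {
  p <- tableParams()
  ss <- steadyState(p)
  tr <- turingCheck(p)
  expect_lt(dispersionRate(p, ss, 0), 0)
  inside <- seq(tr@k2Minus * 1.02, tr@k2Plus * 0.98, length.out = 25)
  expect_true(all(dispersionRate(p, ss, inside) > 0))
  outside <- c(tr@k2Minus * 0.98, tr@k2Plus * 1.02, 1, 10)
  expect_true(all(dispersionRate(p, ss, outside) < 0))
  expect_lt(dispersionRate(p, ss, 1e4), -1e3)
  expect_error(dispersionRate(p, ss, -1), "non-negative")
})

test_that("parameter scaling is exact and rho scales both efficiencies", {
  p <- tableParams()
  expect_equal(scaleParameter(p, "D_A", 1), p)
  expect_equal(scaleParameter(p, "mu_A", 0.4)@mu_A, 0.084)
  pr <- scaleParameter(p, "rho", 2)
  expect_equal(pr@rho_1, 0.4)
  expect_equal(pr@rho_2, 0.4)
  expect_equal(pr@D_A, p@D_A)
  expect_error(scaleParameter(p, "mu_X", 2), "unknown")
  expect_error(scaleParameter(p, "D_A", -1), "positive")
})

test_that("Turing robustness intervals contain the reported range for every
           parameter", {
  p <- tableParams()
  for (nm in c("D_A", "D_H", "mu_A", "mu_H", "rho", "rho_A", "rho_H")) {
    iv <- turingFactorInterval(p, nm)
    expect_lte(iv[["low"]], 0.40)
    expect_gte(iv[["high"]], 2.70)
    expect_true(iv[["low"]] < 1 && 1 < iv[["high"]])
  }
  # the basal inhibitor production barely enters the criteria: its interval
  # spans the whole scan range
  ivh <- turingFactorInterval(p, "rho_H")
  expect_equal(ivh[["low"]], 0.01)
  expect_equal(ivh[["high"]], 10)
})
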