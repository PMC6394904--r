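test_that("initial conditions sit at the steady state plus seeded noise", {
  p <- tableParams()
  r <- ringFromFrontArea(550)
  ss <- steadyState(p)
  f0 <- initialCondition(p, r, simConfig(noiseAmp = 0))
  expect_equal(f0@A, rep(ss@A, 256))
  expect_equal(f0@H, rep(ss@H, 256))
  f1 <- initialCondition(p, r, simConfig(seed = 11))
  f2 <- initialCondition(p, r, simConfig(seed = 11))
  expect_identical(f1@A, f2@A)
  expect_identical(f1@H, f2@H)
  expect_true(all(abs(f1@A - ss@A) <= 5e-4))
  f3 <- initialCondition(p, r, simConfig(seed = 12))
  expect_false(identical(f1@A, f3@A))
  # noise larger than the steady state clips at zero with a warning
  expect_warning(f4 <- initialCondition(p, r, simConfig(noiseAmp = 10)),
                 "clip")
  expect_gte(min(f4@A), 0)
  expect_gt(min(f4@H), 0)
})

test_that("a transient stimulus raises the activator at its centres", {
  p <- tableParams()
  s <- testSphere(550)
  spec <- stimulusSpec("transient", "equatorial", amplitude = 0.5, k = 3)
  stim <- buildStimulus(s, spec)
  cfg <- simConfig(seed = 3)
  f0 <- initialCondition(p, s, cfg, transientStimulus = stim)
  ss <- steadyState(p)
  node <- which.max(stim)
  expect_gt(f0@A[node], ss@A + 0.5 - cfg@noiseAmp - 1e-6)
  expect_error(initialCondition(p, s, cfg, transientStimulus = 1:5),
               "match")
})

test_that("a linearly stable system relaxes to the homogeneous state", {
  p <- tableParams()
  peq <- scaleParameter(p, "D_H", p@D_A / p@D_H)  # equal diffusivities
  r <- ringFromFrontArea(550)
  run <- runOne(peq, r, simConfig(seed = 5))
  expect_true(run$result@converged)
  expect_false(run$result@diverged)
  ss <- steadyState(peq)
  expect_equal(run$result@final@A, rep(ss@A, 256), tolerance = 1e-4)
  expect_equal(patternGeometry(run$label), "none")
})

test_that("the wild-type ring develops a high-contrast pattern", {
  p <- tableParams()
  r <- ringFromFrontArea(550)
  run <- runOne(p, r, simConfig(seed = 2))
  expect_true(run$result@converged)
  fld <- run$result@final
  Astar <- fld@ref[["A"]]
  # the activator falls almost to zero between spikes and rises well above
  # the homogeneous state at spikes
  expect_lt(min(fld@A), 0.1 * Astar)
  expect_gt(max(fld@A), 2 * Astar)
  # the inhibitor never reaches zero anywhere
  expect_gt(min(fld@H), 0.5)
  expect_gte(min(fld@A), 0)
})

test_that("early-time growth of a seeded mode matches the dispersion
           relation within 5 percent", {
  p <- tableParams()
  r <- ringFromFrontArea(550)
  ss <- steadyState(p)
  for (m in c(3, 4)) {
    k2 <- (2 * pi * m / r@length)^2
    lam <- dispersionRate(p, ss, k2)
    meas <- measuredModeGrowth(p, r, m)
    expect_equal(meas, lam, tolerance = 0.05)
  }
})

test_that("simulation replicates are deterministic given the seed", {
  p <- tableParams()
  r <- ringFromFrontArea(550)
  a <- runOne(p, r, simConfig(seed = 21))
  b <- runOne(p, r, simConfig(seed = 21))
  expect_identical(a$result@final@A, b$result@final@A)
  expect_identical(labelString(a$label), labelString(b$label))
  expect_equal(a$result@elapsedModelTime, b$result@elapsedModelTime)
})

test_that("converged and diverged outcomes are mutually exclusive and
           divergence is reported, not thrown", {
  expect_error(new("SimResult",
                   final = initialCondition(tableParams(),
                                            ringFromFrontArea(550),
                                            simConfig(noiseAmp = 0)),
                   converged = TRUE, diverged = TRUE,
                   elapsedModelTime = 1, steps = 1L),
               "mutually exclusive")
})

test_that("steady states persist under spatial refinement on the ring", {
  p <- tableParams()
  for (sd in c(101, 202, 303)) {
    l1 <- runOne(p, ringFromFrontArea(550, 256), simConfig(seed = sd))
    l2 <- runOne(p, ringFromFrontArea(550, 512), simConfig(seed = sd))
    expect_identical(labelString(l1$label), labelString(l2$label))
  }
})
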