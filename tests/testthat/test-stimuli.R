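test_that("the Gaussian bump follows the printed exponential form", {
  s <- testSphere(550)
  v <- s@vertices[17, ]
  f <- gaussianBump(s, v, amplitude = 2.5)
  expect_equal(f[17], 2.5)                        # value at the centre
  # every other node follows exp(-chord^2) with unit (1 um) length scale
  d2 <- rowSums(sweep(s@vertices, 2, v)^2)
  expect_equal(f, 2.5 * exp(-d2))
  # the antipode (chord 2R ~ 26.5 um) is utterly negligible
  anti <- which.min(s@vertices %*% v)
  expect_lt(f[anti], 1e-200)
})

test_that("stimulus patterns have their advertised symmetry", {
  s <- testSphere(550)
  R <- s@radius
  spec3 <- stimulusSpec("transient", "equatorial", 1, k = 3)
  C <- stimulusCenters(s, spec3)
  expect_equal(nrow(C), 3L)
  expect_true(all(abs(rowSums(C^2) - R^2) < 1e-9)) # on the sphere
  expect_true(all(abs(C[, 2]) < 1e-12))            # on the equator
  angs <- apply(utils::combn(3, 2), 2, function(ij)
    acos(sum(C[ij[1], ] * C[ij[2], ]) / R^2) * 180 / pi)
  expect_equal(angs, rep(120, 3), tolerance = 1e-8)
  f3 <- buildStimulus(s, spec3)
  vals <- sapply(seq_len(3), function(i)
    f3[which.min(rowSums(sweep(s@vertices, 2, C[i, ])^2))])
  expect_lt(diff(range(vals)) / mean(vals), 0.05)  # nearest-node sampling
  expect_true(all(f3 >= 0))

  Ct <- stimulusCenters(s, stimulusSpec("continuous", "tetrahedral", 1))
  angs <- apply(utils::combn(4, 2), 2, function(ij)
    acos(sum(Ct[ij[1], ] * Ct[ij[2], ]) / R^2) * 180 / pi)
  expect_equal(angs, rep(109.4712, 6), tolerance = 1e-4)

  fr <- buildStimulus(s, stimulusSpec("transient", "ring", 1))
  eq <- abs(s@vertices[, 2]) < 0.05 * R
  poles <- abs(s@vertices[, 2]) > 0.95 * R
  expect_gt(min(fr[eq]), 0.9)
  expect_lt(max(fr[poles]), 5e-3)
  expect_error(stimulusSpec("transient", "blob", 1), "unknown")
  expect_error(stimulusSpec("sometimes", "ring", 1), "transient")
})

test_that("transient stimuli act only on the initial activator and a zero
           amplitude changes nothing", {
  p <- tableParams()
  s <- testSphere(550)
  cfg <- simConfig(seed = 9)
  base <- initialCondition(p, s, cfg)
  zero <- buildStimulus(s, stimulusSpec("transient", "equatorial", 0, 3))
  with0 <- initialCondition(p, s, cfg, transientStimulus = zero)
  expect_identical(base@A, with0@A)
  expect_identical(base@H, with0@H)
  stim <- buildStimulus(s, stimulusSpec("transient", "equatorial", 1, 3))
  with1 <- initialCondition(p, s, cfg, transientStimulus = stim)
  expect_equal(with1@A - base@A, stim)            # additive on A only
  expect_identical(with1@H, base@H)
})

test_that("a continuous stimulus forces a nonuniform steady state even in
           a linearly stable system", {
  p <- tableParams()
  peq <- scaleParameter(p, "D_H", p@D_A / p@D_H)
  s <- testSphere(550)
  spec <- stimulusSpec("continuous", "equatorial", 0.05, k = 3)
  run <- runOne(peq, s, simConfig(seed = 4, noiseAmp = 0), spec)
  expect_true(run$result@converged)
  fld <- run$result@final
  stim <- buildStimulus(s, spec)
  # the forced steady state is elevated where the forcing acts
  expect_gt(stats::cor(fld@A, stim), 0.5)
  expect_gt(max(fld@A) - min(fld@A), 0.01)
})
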