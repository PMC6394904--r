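sphere550 <- sphereFromFrontArea(550, 3)
sphere750 <- sphereFromFrontArea(750, 3)

test_that("connected components recover synthetic bump and band geometry", {
  lf <- makeLabeledField(sphere550, list(geometry = "equatorial", k = 3),
                         seed = 31)
  comps <- findComponents(lf@field)
  expect_length(comps, 3L)
  # each component centroid sits within a bump width of a true centre
  cen <- do.call(rbind, lapply(comps, `[[`, "centroid")) * sphere550@radius
  d <- apply(cen, 1, function(v)
    min(sqrt(rowSums(sweep(lf@trueLabel@spikeCenters, 2, v)^2))))
  expect_lt(max(d), 3)
  band <- makeLabeledField(sphere550, "ring", seed = 32)
  bc <- findComponents(band@field)
  expect_length(bc, 1L)
  expect_gt(bc[[1]]$coverage, 350)
  # a homogeneous field is one spanning component, gated as unpatterned
  p <- tableParams()
  f0 <- initialCondition(p, sphere550, simConfig(noiseAmp = 0, seed = 1))
  expect_length(findComponents(f0), 1L)
  expect_equal(patternGeometry(classifyPattern(f0)), "none")
})

test_that("the decision cascade labels every synthetic archetype", {
  cases <- list(
    list(req = list(geometry = "equatorial", k = 3), n = 3L),
    list(req = list(geometry = "equatorial", k = 4), n = 4L),
    list(req = "tetrahedral", n = 4L),
    list(req = "polar", n = 2L),
    list(req = "ring", n = 0L),
    list(req = "spike_plus_ring", n = 1L),
    list(req = list(geometry = "other_spikes", k = 5), n = 5L),
    list(req = "elongated_tetra_edges", n = 6L),
    list(req = "none", n = 0L),
    list(req = "failed", n = 0L))
  for (cs in cases) {
    lf <- makeLabeledField(sphere750, cs$req, seed = 77)
    lab <- classifyPattern(lf@field)
    expect_identical(patternGeometry(lab),
                     patternGeometry(lf@trueLabel))
    expect_identical(spikeCount(lab), cs$n)
  }
})

test_that("classification is invariant under the template orientation", {
  for (req in list(list(geometry = "equatorial", k = 3), "tetrahedral",
                   "ring", "spike_plus_ring")) {
    labs <- sapply(c(5, 17, 91), function(sd)
      labelString(classifyPattern(
        makeLabeledField(sphere550, req, seed = sd)@field)))
    expect_length(unique(labs), 1L)
  }
})

test_that("equatorial spike centres come back equally spaced", {
  lf <- makeLabeledField(sphere550, list(geometry = "equatorial", k = 3),
                         seed = 13)
  lab <- classifyPattern(lf@field)
  u <- lab@spikeCenters / sphere550@radius
  angs <- sort(apply(utils::combn(3, 2), 2, function(ij)
    acos(pmin(1, sum(u[ij[1], ] * u[ij[2], ]))) * 180 / pi))
  expect_true(all(abs(angs - 120) <= 10))
})

test_that("ring-domain spike counting handles wraparound, plateaus and
           degenerate fields", {
  r <- ringFromFrontArea(550)
  p <- tableParams()
  ss <- steadyState(p)
  mkf <- function(A) new("Field", domain = r, A = A,
                         H = rep(ss@H, r@nNodes), time = NA_real_,
                         ref = c(A = ss@A, H = ss@H), meta = list())
  # constant field: unpatterned
  expect_equal(as.integer(countSpikesRing(mkf(rep(ss@A, 256)))), 0L)
  # three-mode eigenpattern: three spikes
  x <- r@positions
  f3 <- mkf(ss@A * (1.1 + cos(3 * 2 * pi * x / r@length)))
  expect_equal(as.integer(countSpikesRing(f3)), 3L)
  # a spike centred at the origin wraps around the period seam
  fw <- mkf(ss@A * (1.1 + cos(2 * pi * x / r@length)^8))
  expect_equal(as.integer(countSpikesRing(fw)), 1L)
  # two local maxima on one super-threshold plateau merge into one spike
  bump <- exp(-((x - 40) / 4)^2)
  double <- 4 * ss@A * (bump + 0.02 * sin(2 * pi * x)) + ss@A
  expect_equal(as.integer(countSpikesRing(mkf(double))), 1L)
  # non-finite fields are failures
  Abad <- rep(ss@A, 256); Abad[5] <- NaN
  expect_identical(patternGeometry(classifyPattern(mkf(Abad))), "failed")
})

test_that("synthetic ring fields close the loop through the counter", {
  r <- ringFromFrontArea(550)
  for (k in c(2L, 3L, 5L)) {
    lf <- makeLabeledField(r, list(geometry = "equatorial", k = k),
                           seed = 40 + k)
    expect_equal(as.integer(countSpikesRing(lf@field)), k)
    lab <- classifyPattern(lf@field)
    expect_equal(spikeCount(lab), k)
  }
})
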