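test_that("ring geometry follows the front-view area mapping", {
  for (area in c(350, 550, 750)) {
    r <- ringFromFrontArea(area)
    expect_equal(r@length, 2 * sqrt(pi * area))
    expect_equal(r@radius, sqrt(area / pi))
    expect_equal(pi * r@radius^2, area)           # round trip
    expect_equal(r@nNodes, 256L)
    expect_equal(diff(r@positions),
                 rep(r@length / 256, 255))         # uniform, half-open
    expect_lt(max(r@positions), r@length)
  }
  expect_equal(ringFromFrontArea(550)@length, 83.1365, tolerance = 1e-4)
  expect_equal(ringFromFrontArea(350)@length, 66.3191, tolerance = 1e-4)
  expect_equal(ringFromFrontArea(750)@length, 97.0806, tolerance = 1e-4)
  expect_error(ringFromFrontArea(-5), "positive")
  expect_error(ringFromFrontArea(0), "positive")
})

test_that("sphere geometry: radius from front-view area, total surface
           4x the front view", {
  s <- testSphere(550)
  expect_equal(s@radius, sqrt(550 / pi))
  expect_equal(s@radius, 13.2316, tolerance = 1e-4)
  expect_equal(sphereFromFrontArea(750, 2)@radius, 15.4509,
               tolerance = 1e-4)
  # lumped vertex areas tile the sphere: total ~ 4 pi R^2 = 4 x front view
  expect_equal(sum(s@mass) / s@frontArea, 4, tolerance = 0.02)
  expect_true(all(abs(sqrt(rowSums(s@vertices^2)) - s@radius) < 1e-9))
  expect_error(sphereFromFrontArea(-1), "positive")
})

test_that("discrete Laplacians annihilate constants and reproduce
           eigenfunctions", {
  r <- ringFromFrontArea(550)
  expect_equal(applyLaplacian(r, rep(3.7, 256)), rep(0, 256),
               tolerance = 1e-12)
  x <- r@positions
  for (m in c(1, 3, 6)) {
    u <- cos(2 * pi * m * x / r@length)
    expect_equal(applyLaplacian(r, u), -(2 * pi * m / r@length)^2 * u,
                 tolerance = 1e-8)
  }
  s <- sphereFromFrontArea(550, 3)
  n <- nNodes(s)
  expect_equal(applyLaplacian(s, rep(1, n)), rep(0, n), tolerance = 1e-10)
  # spherical harmonics sampled on the mesh: zonal and tesseral, via the
  # associated Legendre functions as an independent oracle
  U <- s@vertices / s@radius
  ct <- U[, 3]
  phi <- atan2(U[, 2], U[, 1])
  for (l in 1:4) for (mm in c(0L, min(l, 2L))) {
    P <- pracma::legendre(l, ct)
    Y <- P[mm + 1, ] * cos(mm * phi)
    lam <- -l * (l + 1) / s@radius^2
    err <- sqrt(sum(s@mass * (applyLaplacian(s, Y) - lam * Y)^2) /
                  sum(s@mass * (lam * Y)^2))
    expect_lt(err, 0.05)
  }
  expect_error(applyLaplacian(r, rep(1, 100)), "match")
  expect_error(applyLaplacian(s, rep(1, 10)), "match")
})

test_that("refining the sphere mesh shrinks Laplacian eigenvalue error at
           the scheme's order", {
  err <- sapply(2:3, function(lev) {
    s <- sphereFromFrontArea(550, lev)
    U <- s@vertices / s@radius
    Y <- (3 * U[, 3]^2 - 1) / 2                   # degree-2 zonal
    lam <- -6 / s@radius^2
    sqrt(sum(s@mass * (applyLaplacian(s, Y) - lam * Y)^2) /
           sum(s@mass * (lam * Y)^2))
  })
  expect_gt(err[1] / err[2], 2)    # at least first order per refinement
})

test_that("admissible modes inside the unstable band match the dispersion
           analysis", {
  p <- tableParams()
  tr <- turingCheck(p)
  # frozen from the dispersion-band oracle: band k2 ~ (0.01275, 0.16664)
  expect_equal(admissibleModes(ringFromFrontArea(550), tr), 2:5)
  expect_true(4 %in% admissibleModes(ringFromFrontArea(750), tr))
  s <- testSphere(550)
  mods <- admissibleModes(s, tr)
  expect_equal(mods, 2:4)   # l(l+1)/R^2 in band for l = 2..4 at 550 um^2
  # an unsatisfied report yields no admissible modes
  peq <- scaleParameter(p, "D_H", p@D_A / p@D_H)
  expect_length(admissibleModes(ringFromFrontArea(550), turingCheck(peq)),
                0)
})

test_that("sphere meshes export as OBJ", {
  s <- testSphere(550, 1L)
  path <- tempfile(fileext = ".obj")
  writeOBJ(s, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "v ")), nNodes(s))
  expect_equal(sum(startsWith(lines, "f ")), nrow(s@faces))
})
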