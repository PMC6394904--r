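# Shared oracles and small builders used across the suite.

tableParams <- function() gmParameters()

# central finite differences of the reaction terms, the independent check
# for the analytic linearization
fdLinearize <- function(params, ss, h = 1e-6) {
  A <- ss@A; H <- ss@H
  fA <- (reactionTerms(params, A + h, H)$dA -
           reactionTerms(params, A - h, H)$dA) / (2 * h)
  fH <- (reactionTerms(params, A, H + h)$dA -
           reactionTerms(params, A, H - h)$dA) / (2 * h)
  gA <- (reactionTerms(params, A + h, H)$dH -
           reactionTerms(params, A - h, H)$dH) / (2 * h)
  gH <- (reactionTerms(params, A, H + h)$dH -
           reactionTerms(params, A, H - h)$dH) / (2 * h)
  c(f_A = fA, f_H = fH, g_A = gA, g_H = gH)
}

# unstable-band endpoints located independently of the quadratic formula:
# sign changes of the dispersion rate bracketed by uniroot
dispersionBandOracle <- function(params) {
  ss <- steadyState(params)
  f <- function(k2) dispersionRate(params, ss, k2)
  grid <- seq(1e-5, 1, length.out = 4000)
  v <- f(grid)
  sgn <- which(diff(sign(v)) != 0)
  stopifnot(length(sgn) == 2)
  c(stats::uniroot(f, grid[c(sgn[1], sgn[1] + 1)], tol = 1e-12)$root,
    stats::uniroot(f, grid[c(sgn[2], sgn[2] + 1)], tol = 1e-12)$root)
}

# random valid parameter set in the neighbourhood of the defaults
randomParams <- function() {
  f <- function(x) x * stats::runif(1, 0.5, 2)
  gmParameters(D_A = f(1.1), D_H = f(54), mu_A = f(0.21), mu_H = f(0.6),
               rho_1 = f(0.2), rho_2 = f(0.2), rho_A = f(0.003),
               rho_H = f(1e-4))
}

# growth rate of ring Fourier mode m measured from a short integration of a
# small single-mode perturbation
measuredModeGrowth <- function(params, domain, m, eps = 1e-6,
                               t1 = 10, t2 = 30, dt = 0.05) {
  ss <- steadyState(params)
  x <- domain@positions
  mk <- function(tstop) {
    f0 <- new("Field", domain = domain,
              A = ss@A + eps * cos(2 * pi * m * x / domain@length),
              H = rep(ss@H, domain@nNodes), time = 0,
              ref = c(A = ss@A, H = ss@H), meta = list())
    cfg <- simConfig(noiseAmp = 0, tMax = tstop, dt = dt, driftDt = dt,
                     steadyTol = 1e-30, checkEvery = 1000L)
    res <- integrateGM(params, f0, cfg)
    amp <- Mod(stats::fft(res@final@A))[m + 1] / domain@nNodes
    amp
  }
  log(mk(t2) / mk(t1)) / (t2 - t1)
}

labelString <- function(label) {
  g <- patternGeometry(label)
  if (g %in% c("none", "ring", "failed")) g
  else paste0(spikeCount(label), "-", g)
}

# deterministic sphere/ring fixtures at reduced resolution for fast tests
testSphere <- function(area = 550, level = 2L) sphereFromFrontArea(area, level)
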