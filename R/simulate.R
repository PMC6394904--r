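#' Noise-perturbed initial conditions
#'
#' Both morphogens start near their diffusion-free steady-state values, with
#' an independent uniform random value in [-noiseAmp, +noiseAmp] added at
#' every node.  A transient stimulus, if given, is added to the activator
#' only.  The same seed always reproduces the same field.
#'
#' @param params a \code{GMParameters} object
#' @param domain a \code{Domain}
#' @param config a \code{SimConfig} (supplies noise amplitude and seed)
#' @param transientStimulus optional per-node field (uM) added to the
#'   activator initial condition
#' @return a \code{Field} at time 0
#' @export
initialCondition <- function(params, domain, config = simConfig(),
                             transientStimulus = NULL) {
  ss <- steadyState(params)
  n <- nNodes(domain)
  set.seed(config@seed)
  A <- ss@A + stats::runif(n, -config@noiseAmp, config@noiseAmp)
  H <- ss@H + stats::runif(n, -config@noiseAmp, config@noiseAmp)
  if (!is.null(transientStimulus)) {
    if (length(transientStimulus) != n)
      stop("transient stimulus length does not match domain")
    A <- A + transientStimulus
  }
  if (any(A < 0) || any(H <= 0)) {
    warning("initial condition clipped at zero (noise exceeds steady state)")
    A <- pmax(A, 0)
    H <- pmax(H, 1e-12)
  }
  new("Field", domain = domain, A = A, H = H, time = 0,
      ref = c(A = ss@A, H = ss@H),
      meta = list(seed = config@seed, noiseAmp = config@noiseAmp,
                  params = .paramsList(params)))
}

.paramsList <- function(params)
  stats::setNames(lapply(gmParameterNames(), function(nm) slot(params, nm)),
                  gmParameterNames())

# implicit diffusion solver factory: returns function(u) solving
# (I - dt D Lap) u_new = u  in the domain's discrete spaces
.diffusionSolver <- function(domain, D, dt) {
  if (is(domain, "RingDomain")) {
    n <- domain@nNodes
    k <- 2 * pi / domain@length * c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    denom <- 1 + dt * D * k^2
    function(u) Re(stats::fft(stats::fft(u) / denom, inverse = TRUE)) / n
  } else {
    M <- Matrix::Diagonal(x = domain@mass)
    K <- M - dt * D * domain@laplacian
    ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(K),
                                       "CsparseMatrix"))
    mass <- domain@mass
    function(u) as.numeric(Matrix::solve(ch, u * mass))
  }
}

#' Integrate the reaction-diffusion system to steady state
#'
#' Advances dA/dt = D_A Lap A + f(A,H) + F(x) and
#' dH/dt = D_H Lap H + g(A,H) with an IMEX Euler scheme: diffusion is
#' treated implicitly (backward Euler; exact tridiagonal-free solve by FFT on
#' the ring, cached sparse Cholesky on the sphere), reaction explicitly.
#' The scheme's fixed point is the exact discrete steady state, so the
#' stopping criterion can be evaluated on the true right-hand side: the run
#' stops once max |dA/dt|/A* and max |dH/dt|/H* stay below
#' \code{config@steadyTol} for \code{config@steadyWindow} seconds.  If a
#' non-finite value or a runaway activator (> 1e6 A*) appears, the run is
#' reported as diverged rather than raising an error.
#'
#' @param params a \code{GMParameters} object
#' @param field the initial \code{Field}
#' @param config a \code{SimConfig}
#' @param continuousStimulus optional per-node forcing (uM/s) added to
#'   dA/dt at every step
#' @return a \code{SimResult}
#' @export
integrateGM <- function(params, field, config = simConfig(),
                        continuousStimulus = NULL) {
  res <- .integrateCore(params, field, config, continuousStimulus)
  if (res$diverged && res$driftEngaged && config@driftDt > config@dt) {
    # the large drift step can overshoot for fast kinetics; retry the
    # whole run without acceleration before reporting a divergence
    safe <- config; safe@driftDt <- config@dt
    res <- .integrateCore(params, field, safe, continuousStimulus)
  }
  new("SimResult", final = res$final, converged = res$converged,
      diverged = res$diverged, elapsedModelTime = res$t,
      steps = res$steps)
}

.integrateCore <- function(params, field, config, continuousStimulus) {
  domain <- field@domain
  n <- nNodes(domain)
  Fx <- if (is.null(continuousStimulus)) 0 else {
    if (length(continuousStimulus) != n)
      stop("continuous stimulus length does not match domain")
    continuousStimulus
  }
  dt <- config@dt
  solveA <- .diffusionSolver(domain, params@D_A, dt)
  solveH <- .diffusionSolver(domain, params@D_H, dt)
  drifting <- config@driftDt <= dt   # nothing to switch to
  # a Turing-unstable domain must not be declared converged while still
  # (near-)homogeneous: band modes grow from minute amplitudes whose rates
  # can transiently sit below the tolerance
  expectPattern <- local({
    tc <- tryCatch(turingCheck(params), error = function(e) NULL)
    !is.null(tc) && isTRUE(tc@satisfied) &&
      length(admissibleModes(domain, tc)) > 0L
  })
  A <- field@A; H <- field@H
  Astar <- field@ref[["A"]]; Hstar <- field@ref[["H"]]
  mu_A <- params@mu_A; mu_H <- params@mu_H
  rho_1 <- params@rho_1; rho_2 <- params@rho_2
  rho_A <- params@rho_A; rho_H <- params@rho_H
  maxA <- 1e6 * Astar
  t <- 0; step <- 0L
  belowSince <- NA_real_
  converged <- FALSE; diverged <- FALSE
  nmax <- ceiling(config@tMax / dt)
  while (step < nmax) {
    RA <- -mu_A * A + rho_1 * (A + rho_A)^2 / H + Fx
    RH <- -mu_H * H + rho_2 * A^2 + rho_H
    A <- solveA(A + dt * RA)
    H <- solveH(H + dt * RH)
    step <- step + 1L
    t <- t + dt
    if (step %% config@checkEvery == 0L || step == nmax) {
      if (!all(is.finite(A)) || !all(is.finite(H)) ||
          max(A) > maxA || any(H <= 0)) {
        diverged <- TRUE
        break
      }
      dA <- params@D_A * applyLaplacian(domain, A) +
        (-mu_A * A + rho_1 * (A + rho_A)^2 / H + Fx)
      dH <- params@D_H * applyLaplacian(domain, H) +
        (-mu_H * H + rho_2 * A^2 + rho_H)
      rrate <- max(max(abs(dA)) / Astar, max(abs(dH)) / Hstar)
      below <- rrate < config@steadyTol
      if (below && expectPattern && max(A) - min(A) < 0.5 * Astar)
        below <- FALSE                 # pattern still pending
      if (!drifting && rrate < config@driftThreshold &&
          max(A) > 2 * Astar) {
        dt <- config@driftDt
        solveA <- .diffusionSolver(domain, params@D_A, dt)
        solveH <- .diffusionSolver(domain, params@D_H, dt)
        nmax <- step + ceiling((config@tMax - t) / dt)
        drifting <- TRUE
      }
      if (below) {
        if (is.na(belowSince)) belowSince <- t
        if (t - belowSince >= config@steadyWindow) {
          converged <- TRUE
          break
        }
      } else belowSince <- NA_real_
    }
  }
  final <- new("Field", domain = domain, A = A, H = H, time = t,
               ref = field@ref, meta = field@meta)
  list(final = final, converged = converged, diverged = diverged,
       t = t, steps = step, driftEngaged = drifting && !
         (config@driftDt <= config@dt))
}

#' Run one replicate: initial condition, integration, classification
#'
#' Composes \code{\link{initialCondition}}, \code{\link{integrateGM}} and
#' \code{\link{classifyPattern}} for a single simulation replicate.  A
#' transient stimulus perturbs the activator initial condition; a continuous
#' stimulus adds a forcing term to the activator equation for the whole
#' run.  Diverged runs are labeled \code{"failed"}.
#'
#' @param params a \code{GMParameters} object
#' @param domain a \code{Domain}
#' @param config a \code{SimConfig}
#' @param stimulus optional \code{StimulusSpec}
#' @return list with elements \code{result} (\code{SimResult}) and
#'   \code{label} (\code{PatternLabel})
#' @examples
#' \donttest{
#' run <- runOne(gmParameters(), ringFromFrontArea(550),
#'               simConfig(seed = 7))
#' run$label
#' }
#' @export
runOne <- function(params, domain, config = simConfig(), stimulus = NULL) {
  transient <- continuous <- NULL
  if (!is.null(stimulus)) {
    stopifnot(is(stimulus, "StimulusSpec"))
    fieldvals <- buildStimulus(domain, stimulus)
    if (stimulus@mode == "transient") transient <- fieldvals
    else continuous <- fieldvals
  }
  f0 <- initialCondition(params, domain, config, transient)
  res <- integrateGM(params, f0, config, continuous)
  label <- if (res@diverged)
    new("PatternLabel", nSpikes = 0L, geometry = "failed",
        spikeCenters = matrix(numeric(0), 0, 3),
        metadata = list(diverged = TRUE))
  else classifyPattern(res@final)
  list(result = res, label = label)
}
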