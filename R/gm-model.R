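#' Reaction terms of the activator-inhibitor kinetics
#'
#' Evaluates the diffusion-free right-hand sides
#' \deqn{f(A,H) = -\mu_A A + \rho_1 (A+\rho_A)^2 / H}
#' \deqn{g(A,H) = -\mu_H H + \rho_2 A^2 + \rho_H}
#' The activator autocatalysis is damped by the inhibitor through the 1/H
#' factor, which is why the inhibitor must stay positive.
#'
#' @param params a \code{\link{gmParameters}} object
#' @param A activator concentration(s), uM
#' @param H inhibitor concentration(s), uM; must be strictly positive
#' @return list with components \code{dA} and \code{dH} (uM/s)
#' @examples
#' reactionTerms(gmParameters(), A = 0, H = 1)
#' @export
reactionTerms <- function(params, A, H) {
  if (any(H <= 0))
    stop("inhibitor concentration must be strictly positive (division by H)")
  dA <- -params@mu_A * A + params@rho_1 * (A + params@rho_A)^2 / H
  dH <- -params@mu_H * H + params@rho_2 * A^2 + params@rho_H
  list(dA = dA, dH = dH)
}

#' Homogeneous steady state of the kinetics
#'
#' Solves the diffusion-free system f(A,H) = g(A,H) = 0 for its positive
#' root, retaining the basal terms.  Eliminating H through
#' H = (rho_2 A^2 + rho_H)/mu_H leaves a scalar root-finding problem in A,
#' solved by Newton iteration started from the closed form
#' A = rho_1 mu_H / (rho_2 mu_A) that holds when both basal terms vanish.
#'
#' @param params a \code{GMParameters} object
#' @param tol residual tolerance on both reaction terms (uM/s)
#' @return a \code{GMSteadyState}
#' @examples
#' steadyState(gmParameters())
#' @export
steadyState <- function(params, tol = 1e-12) {
  Hof <- function(A) (params@rho_2 * A^2 + params@rho_H) / params@mu_H
  f <- function(A) -params@mu_A * A +
    params@rho_1 * (A + params@rho_A)^2 / Hof(A)
  A0 <- params@rho_1 * params@mu_H / (params@rho_2 * params@mu_A)
  A <- A0
  for (i in seq_len(100)) {
    fa <- f(A)
    if (abs(fa) < tol) break
    h <- max(1e-8, abs(A) * 1e-7)
    dfa <- (f(A + h) - f(A - h)) / (2 * h)
    step <- fa / dfa
    Anew <- A - step
    if (!is.finite(Anew) || Anew <= 0) Anew <- A / 2
    A <- Anew
  }
  if (!is.finite(A) || A <= 0 || abs(f(A)) > 1e-8)
    stop(sprintf(paste0("no positive homogeneous steady state found ",
                        "(residual %.3g at A = %.3g); the kinetics do not ",
                        "balance"), f(A), A))
  new("GMSteadyState", A = A, H = Hof(A))
}

#' Linearize the kinetics at the steady state
#'
#' Analytic partial derivatives of the reaction terms at (A*, H*).  The
#' activator-inhibitor sign structure (self-activation f_A > 0, inhibition
#' f_H < 0, cross-activation g_A > 0, linear inhibitor decay g_H = -mu_H)
#' is what permits diffusion-driven instability.
#'
#' @param params a \code{GMParameters} object
#' @param ss a \code{GMSteadyState}; computed from \code{params} if missing
#' @return a \code{GMLinearization}
#' @export
linearize <- function(params, ss = steadyState(params)) {
  A <- ss@A; H <- ss@H
  f_A <- -params@mu_A + 2 * params@rho_1 * (A + params@rho_A) / H
  f_H <- -params@rho_1 * (A + params@rho_A)^2 / H^2
  g_A <- 2 * params@rho_2 * A
  g_H <- -params@mu_H
  new("GMLinearization", f_A = f_A, f_H = f_H, g_A = g_A, g_H = g_H,
      trace = f_A + g_H, det = f_A * g_H - f_H * g_A)
}

#' Test the Turing-instability criteria
#'
#' Evaluates the four standard two-species conditions for diffusion-driven
#' instability of the homogeneous steady state:
#' trace < 0, det > 0, D_H f_A + D_A g_H > 0, and
#' (D_H f_A + D_A g_H)^2 > 4 D_A D_H det.  When all four hold, the unstable
#' squared-wavenumber band (k2Minus, k2Plus) is given by the roots of
#' D_A D_H k^4 - (D_H f_A + D_A g_H) k^2 + det = 0.
#'
#' @param params a \code{GMParameters} object
#' @return a \code{\linkS4class{TuringReport}}
#' @examples
#' turingCheck(gmParameters())
#' @export
turingCheck <- function(params) {
  ss <- steadyState(params)
  lin <- linearize(params, ss)
  stable <- lin@trace < 0 && lin@det > 0
  b <- params@D_H * lin@f_A + params@D_A * lin@g_H
  disc <- b^2 - 4 * params@D_A * params@D_H * lin@det
  ddi <- b > 0 && disc > 0
  satisfied <- stable && ddi
  if (satisfied) {
    s <- sqrt(disc)
    k2m <- (b - s) / (2 * params@D_A * params@D_H)
    k2p <- (b + s) / (2 * params@D_A * params@D_H)
  } else k2m <- k2p <- NA_real_
  new("TuringReport", stableWithoutDiffusion = stable,
      diffusionDrivenInstability = ddi, k2Minus = k2m, k2Plus = k2p,
      satisfied = satisfied, linearization = lin, steadyState = ss)
}

#' Linear growth rate of a spatial perturbation
#'
#' The dispersion relation: the larger real part of the eigenvalues of the
#' Jacobian \code{[[f_A - D_A k2, f_H], [g_A, g_H - D_H k2]]} as a function
#' of the squared wavenumber.  Positive values identify spontaneously
#' growing spatial modes.
#'
#' @param params a \code{GMParameters} object
#' @param ss a \code{GMSteadyState}; computed if missing
#' @param k2 squared wavenumber(s), 1/um^2, each >= 0
#' @return growth rate(s) in 1/s (vectorized over \code{k2})
#' @export
dispersionRate <- function(params, ss = steadyState(params), k2) {
  if (any(k2 < 0)) stop("k2 must be non-negative")
  lin <- linearize(params, ss)
  a11 <- lin@f_A - params@D_A * k2
  a22 <- lin@g_H - params@D_H * k2
  tr <- a11 + a22
  dt <- a11 * a22 - lin@f_H * lin@g_A
  disc <- tr^2 - 4 * dt
  ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
}

#' Scale one kinetic parameter
#'
#' Returns a copy of the parameter set with the named parameter multiplied
#' by \code{factor}.  The name \code{"rho"} scales \code{rho_1} and
#' \code{rho_2} jointly, since the two reaction efficiencies share one
#' magnitude and are swept together.
#'
#' @param params a \code{GMParameters} object
#' @param name one of \code{gmParameterNames()} or \code{"rho"}
#' @param factor positive multiplicative factor
#' @return a new \code{GMParameters}
#' @examples
#' scaleParameter(gmParameters(), "mu_A", 0.4)@mu_A  # 0.084
#' @export
scaleParameter <- function(params, name, factor) {
  if (factor <= 0) stop("factor must be positive")
  if (identical(name, "rho")) {
    params@rho_1 <- params@rho_1 * factor
    params@rho_2 <- params@rho_2 * factor
  } else if (name %in% gmParameterNames()) {
    slot(params, name) <- slot(params, name) * factor
  } else stop(sprintf("unknown parameter name '%s'", name))
  validObject(params)
  params
}

#' Robustness interval of a parameter within the Turing regime
#'
#' Finds the contiguous interval of multiplicative scaling factors,
#' containing 1, over which \code{\link{turingCheck}} remains satisfied when
#' the named parameter is scaled alone.  Located by a multiplicative grid
#' scan refined by bisection to relative precision \code{relTol}.  The scan
#' is bounded by \code{[floorFactor, capFactor]}; an endpoint equal to a
#' bound means the regime extends at least that far.
#'
#' @param params a \code{GMParameters} satisfying the Turing criteria
#' @param name parameter name (see \code{\link{scaleParameter}})
#' @param floorFactor,capFactor scan bounds
#' @param relTol relative precision of the bisection
#' @return numeric \code{c(low =, high =)} scaling factors
#' @export
turingFactorInterval <- function(params, name, floorFactor = 0.01,
                                 capFactor = 10, relTol = 1e-3) {
  ok <- function(f) {
    r <- tryCatch(turingCheck(scaleParameter(params, name, f)),
                  error = function(e) NULL)
    !is.null(r) && isTRUE(r@satisfied)
  }
  if (!ok(1)) stop("base parameters do not satisfy the Turing criteria")
  bisect <- function(good, bad) {
    # invariant: ok(good), !ok(bad)
    while (abs(bad - good) > relTol * good) {
      mid <- sqrt(good * bad)
      if (ok(mid)) good <- mid else bad <- mid
    }
    good
  }
  scan <- function(direction) {
    f <- 1
    step <- if (direction > 0) 1.05 else 1 / 1.05
    repeat {
      nxt <- f * step
      if (nxt > capFactor || nxt < floorFactor) {
        bound <- if (direction > 0) capFactor else floorFactor
        return(if (ok(bound)) bound else bisect(f, bound))
      }
      if (!ok(nxt)) return(bisect(f, nxt))
      f <- nxt
    }
  }
  c(low = scan(-1), high = scan(+1))
}
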