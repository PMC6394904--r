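#' @import methods
#' @importFrom stats runif fft setNames
#' @importFrom Matrix sparseMatrix Diagonal Cholesky solve t
NULL

#' Kinetic parameters of the activator-inhibitor system
#'
#' Holds the eight kinetic constants of the Gierer-Meinhardt system used to
#' model pollen aperture patterning: diffusion (um^2/s) and decay (1/s) of the
#' activator and the inhibitor, the two reaction-rate constants, and the two
#' basal production terms.  Defaults are the wild-type parameterization.
#'
#' @slot D_A activator diffusion constant (um^2/s)
#' @slot D_H inhibitor diffusion constant (um^2/s)
#' @slot mu_A activator decay rate (1/s)
#' @slot mu_H inhibitor decay rate (1/s)
#' @slot rho_1 reaction rate of the activator autocatalysis (1/s)
#' @slot rho_2 reaction rate of the inhibitor production (1/(uM s))
#' @slot rho_A basal activator production offset (uM)
#' @slot rho_H basal inhibitor production (uM/s)
#' @exportClass GMParameters
setClass("GMParameters",
  representation(D_A = "numeric", D_H = "numeric",
                 mu_A = "numeric", mu_H = "numeric",
                 rho_1 = "numeric", rho_2 = "numeric",
                 rho_A = "numeric", rho_H = "numeric"),
  validity = function(object) {
    v <- unlist(lapply(gmParameterNames(), function(nm) slot(object, nm)))
    if (length(v) != 8L || any(!is.finite(v)))
      return("all eight parameters must be finite scalars")
    if (any(v <= 0))
      return(paste("parameters must be strictly positive:",
                   paste(gmParameterNames()[v <= 0], collapse = ", ")))
    TRUE
  })

#' Names of the eight kinetic parameters
#' @return character vector of slot names of a \code{GMParameters} object
#' @export
gmParameterNames <- function()
  c("D_A", "D_H", "mu_A", "mu_H", "rho_1", "rho_2", "rho_A", "rho_H")

#' Construct a parameter set
#'
#' Defaults are the wild-type values that reproduce the three-aperture
#' pattern of Arabidopsis pollen.
#'
#' @param D_A,D_H diffusion constants (um^2/s)
#' @param mu_A,mu_H decay rates (1/s)
#' @param rho_1,rho_2 reaction rates (1/s and 1/(uM s)); equal in magnitude
#'   in the wild-type parameterization
#' @param rho_A basal activator offset (uM)
#' @param rho_H basal inhibitor production (uM/s)
#' @return a \code{GMParameters} object
#' @examples
#' p <- gmParameters()
#' p
#' @export
gmParameters <- function(D_A = 1.1, D_H = 54, mu_A = 0.21, mu_H = 0.6,
                         rho_1 = 0.2, rho_2 = 0.2, rho_A = 0.003,
                         rho_H = 1e-4) {
  new("GMParameters", D_A = D_A, D_H = D_H, mu_A = mu_A, mu_H = mu_H,
      rho_1 = rho_1, rho_2 = rho_2, rho_A = rho_A, rho_H = rho_H)
}

setMethod("show", "GMParameters", function(object) {
  cat("GMParameters (activator-inhibitor kinetics)\n")
  for (nm in gmParameterNames())
    cat(sprintf("  %-6s %g\n", nm, slot(object, nm)))
})

#' Homogeneous (diffusion-free) steady state
#' @slot A activator concentration (uM)
#' @slot H inhibitor concentration (uM)
#' @exportClass GMSteadyState
setClass("GMSteadyState", representation(A = "numeric", H = "numeric"),
  validity = function(object) {
    if (object@A <= 0 || object@H <= 0) return("steady state must be positive")
    TRUE
  })

setMethod("show", "GMSteadyState", function(object)
  cat(sprintf("GMSteadyState: A* = %.6g uM, H* = %.6g uM\n",
              object@A, object@H)))

#' Linearization of the reaction kinetics at the steady state
#'
#' Partial derivatives of the two reaction terms with respect to the two
#' morphogens, evaluated at the homogeneous steady state, together with the
#' trace and determinant of the reaction Jacobian.
#'
#' @slot f_A,f_H derivatives of the activator reaction term (1/s)
#' @slot g_A,g_H derivatives of the inhibitor reaction term (1/s)
#' @slot trace,det trace and determinant of the Jacobian
#' @exportClass GMLinearization
setClass("GMLinearization",
  representation(f_A = "numeric", f_H = "numeric", g_A = "numeric",
                 g_H = "numeric", trace = "numeric", det = "numeric"))

setMethod("show", "GMLinearization", function(object)
  cat(sprintf(paste0("GMLinearization: f_A=%.5g f_H=%.5g g_A=%.5g g_H=%.5g",
                     "  (tr=%.5g, det=%.5g)\n"),
              object@f_A, object@f_H, object@g_A, object@g_H,
              object@trace, object@det)))

#' Result of the Turing-instability test
#'
#' Reports whether a parameter set sits in the diffusion-driven
#' pattern-forming regime and, if so, the band of unstable squared
#' wavenumbers.
#'
#' @slot stableWithoutDiffusion homogeneous state is linearly stable without
#'   diffusion (trace < 0 and det > 0)
#' @slot diffusionDrivenInstability diffusion destabilizes some wavenumber
#' @slot k2Minus,k2Plus bounds of the unstable squared-wavenumber band
#'   (1/um^2); \code{NA} when the criteria are not satisfied
#' @slot satisfied all four Turing inequalities hold
#' @slot linearization the \code{GMLinearization} used
#' @slot steadyState the \code{GMSteadyState} used
#' @exportClass TuringReport
setClass("TuringReport",
  representation(stableWithoutDiffusion = "logical",
                 diffusionDrivenInstability = "logical",
                 k2Minus = "numeric", k2Plus = "numeric",
                 satisfied = "logical",
                 linearization = "GMLinearization",
                 steadyState = "GMSteadyState"))

setMethod("show", "TuringReport", function(object) {
  cat("TuringReport\n")
  cat("  stable without diffusion:", object@stableWithoutDiffusion, "\n")
  cat("  diffusion-driven instability:", object@diffusionDrivenInstability, "\n")
  if (isTRUE(object@satisfied))
    cat(sprintf("  unstable band: k2 in (%.5g, %.5g) 1/um^2\n",
                object@k2Minus, object@k2Plus))
  cat("  satisfied:", object@satisfied, "\n")
})

#' Spatial domains
#'
#' \code{RingDomain} is a uniformly discretized periodic 1D domain
#' representing the pollen equator; \code{SphereDomain} is a subdivided
#' icosahedral triangulation of the microspore surface carrying a
#' cotangent-weight Laplace-Beltrami operator.  Both are constructed from the
#' front-view (projected disc) area of the grain, pi R^2.
#'
#' @slot frontArea projected front-view area (um^2)
#' @slot radius sphere radius (um)
#' @aliases RingDomain-class SphereDomain-class
#' @exportClass Domain
setClass("Domain", representation("VIRTUAL",
  frontArea = "numeric", radius = "numeric"))

#' @slot length ring circumference (um)
#' @slot nNodes number of grid nodes
#' @slot positions arc-length node coordinates in [0, length) (um)
#' @rdname Domain-class
#' @exportClass RingDomain
setClass("RingDomain", contains = "Domain",
  representation(length = "numeric", nNodes = "integer",
                 positions = "numeric"),
  validity = function(object) {
    if (object@frontArea <= 0) return("frontArea must be positive")
    if (object@nNodes < 32L) return("nNodes must be at least 32")
    if (abs(object@length - 2 * pi * object@radius) > 1e-8 * object@length)
      return("length must equal 2*pi*radius")
    TRUE
  })

#' @slot level icosphere subdivision level
#' @slot vertices n x 3 matrix of node positions (um); the y axis is the
#'   polar axis, the y = 0 plane the equator
#' @slot faces triangle index matrix
#' @slot laplacian sparse cotangent-weight stiffness matrix
#' @slot mass lumped (barycentric) vertex areas (um^2)
#' @rdname Domain-class
#' @exportClass SphereDomain
setClass("SphereDomain", contains = "Domain",
  representation(level = "integer", vertices = "matrix", faces = "matrix",
                 laplacian = "Matrix", mass = "numeric"),
  validity = function(object) {
    if (object@frontArea <= 0) return("frontArea must be positive")
    if (nrow(object@vertices) != length(object@mass))
      return("mass vector must match vertex count")
    TRUE
  })

setMethod("show", "RingDomain", function(object)
  cat(sprintf(paste0("RingDomain: front area %.4g um^2, circumference",
                     " %.4g um, %d nodes\n"),
              object@frontArea, object@length, object@nNodes)))

setMethod("show", "SphereDomain", function(object)
  cat(sprintf(paste0("SphereDomain: front area %.4g um^2, radius %.4g um,",
                     " level %d (%d vertices)\n"),
              object@frontArea, object@radius, object@level,
              nrow(object@vertices))))

#' Number of nodes of a domain
#' @param object a \code{Domain}
#' @return integer node count
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
#' @rdname nNodes
setMethod("nNodes", "RingDomain", function(object) object@nNodes)
#' @rdname nNodes
setMethod("nNodes", "SphereDomain", function(object)
  nrow(object@vertices))

#' Front-view area of a domain
#' @param object a \code{Domain}
#' @return front-view (projected disc) area in um^2
#' @export
setGeneric("frontArea", function(object) standardGeneric("frontArea"))
#' @rdname frontArea
setMethod("frontArea", "Domain", function(object) object@frontArea)

#' Morphogen concentration field on a domain
#'
#' Per-node activator and inhibitor concentrations at one time point.  The
#' reference homogeneous steady state travels with the field so that the
#' pattern classifier can express its contrast gates in units of A*.
#'
#' @slot domain the \code{Domain} the field lives on
#' @slot A,H per-node activator / inhibitor concentrations (uM)
#' @slot time model time (s)
#' @slot ref named numeric, reference steady state \code{c(A =, H =)}
#' @slot meta list of provenance (seed, parameter signature, ...)
#' @exportClass Field
setClass("Field",
  representation(domain = "Domain", A = "numeric", H = "numeric",
                 time = "numeric", ref = "numeric", meta = "list"),
  validity = function(object) {
    n <- nNodes(object@domain)
    if (length(object@A) != n || length(object@H) != n)
      return("A and H must have one value per domain node")
    TRUE
  })

setMethod("show", "Field", function(object) {
  cat(sprintf("Field at t = %.4g s on ", object@time))
  show(object@domain)
  cat(sprintf("  A in [%.4g, %.4g] uM; H in [%.4g, %.4g] uM\n",
              min(object@A), max(object@A), min(object@H), max(object@H)))
})

#' Activator / inhibitor accessors
#' @param object a \code{Field}
#' @return numeric vector of per-node concentrations (uM)
#' @export
setGeneric("activator", function(object) standardGeneric("activator"))
#' @rdname activator
setMethod("activator", "Field", function(object) object@A)
#' @rdname activator
#' @export
setGeneric("inhibitor", function(object) standardGeneric("inhibitor"))
#' @rdname activator
setMethod("inhibitor", "Field", function(object) object@H)

#' Simulation configuration
#'
#' @slot noiseAmp amplitude of the uniform noise added to the initial
#'   conditions (uM); the wild-type protocol uses 5e-4
#' @slot seed integer seed for the replicate's random stream
#' @slot tMax maximum model time (s)
#' @slot steadyTol steady-state criterion: largest relative rate
#'   max |du/dt| / u* below this value (1/s)
#' @slot steadyWindow time (s) the criterion must hold before stopping
#' @slot dt IMEX time step (s) during pattern formation
#' @slot driftDt larger time step (s) used once the pattern has formed and
#'   relative rates have fallen below \code{driftThreshold}; the IMEX fixed
#'   point (the discrete steady state) does not depend on the step size, so
#'   this only accelerates the slow spike-drift phase
#' @slot driftThreshold relative rate (1/s) below which the drift step is
#'   engaged
#' @slot checkEvery steps between convergence checks
#' @exportClass SimConfig
setClass("SimConfig",
  representation(noiseAmp = "numeric", seed = "integer", tMax = "numeric",
                 steadyTol = "numeric", steadyWindow = "numeric",
                 dt = "numeric", driftDt = "numeric",
                 driftThreshold = "numeric", checkEvery = "integer"),
  validity = function(object) {
    if (object@noiseAmp < 0) return("noiseAmp must be >= 0")
    if (object@steadyTol <= 0) return("steadyTol must be > 0")
    if (object@dt <= 0) return("dt must be > 0")
    TRUE
  })

#' Construct a simulation configuration
#' @param noiseAmp initial-condition noise amplitude (uM)
#' @param seed integer seed
#' @param tMax maximum model time (s)
#' @param steadyTol relative steady-state rate threshold (1/s)
#' @param steadyWindow duration (s) the threshold must hold
#' @param dt time step (s) during pattern formation
#' @param driftDt time step (s) for the slow spike-drift phase
#' @param driftThreshold relative rate (1/s) switching to the drift step
#' @param checkEvery steps between convergence checks
#' @return a \code{SimConfig}
#' @export
simConfig <- function(noiseAmp = 5e-4, seed = 1L, tMax = 1e5,
                      steadyTol = 1e-6, steadyWindow = 10, dt = 0.25,
                      driftDt = 2, driftThreshold = 1e-3,
                      checkEvery = 40L) {
  new("SimConfig", noiseAmp = noiseAmp, seed = as.integer(seed), tMax = tMax,
      steadyTol = steadyTol, steadyWindow = steadyWindow, dt = dt,
      driftDt = driftDt, driftThreshold = driftThreshold,
      checkEvery = as.integer(checkEvery))
}

setMethod("show", "SimConfig", function(object)
  cat(sprintf(paste0("SimConfig: noise %.3g uM, seed %d, tMax %.3g s, ",
                     "tol %.1g 1/s, dt %.3g s\n"),
              object@noiseAmp, object@seed, object@tMax, object@steadyTol,
              object@dt)))

#' Result of one integration
#' @slot final the final \code{Field}
#' @slot converged steady-state criterion met before \code{tMax}
#' @slot diverged non-finite or runaway values appeared
#' @slot elapsedModelTime model time integrated (s)
#' @slot steps number of time steps taken
#' @exportClass SimResult
setClass("SimResult",
  representation(final = "Field", converged = "logical",
                 diverged = "logical", elapsedModelTime = "numeric",
                 steps = "integer"),
  validity = function(object) {
    if (isTRUE(object@converged) && isTRUE(object@diverged))
      return("converged and diverged are mutually exclusive")
    TRUE
  })

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %s after %.4g s (%d steps)\n",
              if (object@diverged) "DIVERGED"
              else if (object@converged) "converged"
              else "tMax reached", object@elapsedModelTime, object@steps))
  show(object@final)
})

#' Stimulus specification
#'
#' Spatial stimulus applied on the sphere, either transiently (added once to
#' the activator initial condition, amplitude in uM) or continuously (a
#' forcing term added to dA/dt for the whole run, amplitude in uM/s).  The
#' inhibitor is never stimulated.
#'
#' @slot mode \code{"transient"} or \code{"continuous"}
#' @slot pattern one of \code{"equatorial"}, \code{"tetrahedral"},
#'   \code{"ring"}, \code{"uniform"}
#' @slot k number of spikes for the equatorial pattern (1-4)
#' @slot amplitude stimulus amplitude (uM or uM/s)
#' @slot width Gaussian width of the stimulus features (um); defaults to
#'   the intrinsic spike half-width so stimuli resemble the model's own
#'   spike patterns
#' @exportClass StimulusSpec
setClass("StimulusSpec",
  representation(mode = "character", pattern = "character", k = "integer",
                 amplitude = "numeric", width = "numeric"),
  validity = function(object) {
    if (!object@mode %in% c("transient", "continuous"))
      return("mode must be 'transient' or 'continuous'")
    if (!object@pattern %in% c("equatorial", "tetrahedral", "ring", "uniform"))
      return("unknown stimulus pattern")
    if (object@amplitude < 0) return("amplitude must be non-negative")
    if (object@width <= 0) return("width must be positive")
    if (object@pattern == "equatorial" &&
        (object@k < 1L || object@k > 4L))
      return("equatorial stimuli support 1 to 4 spikes")
    TRUE
  })

#' Construct a stimulus specification
#' @param mode \code{"transient"} or \code{"continuous"}
#' @param pattern \code{"equatorial"}, \code{"tetrahedral"}, \code{"ring"}
#'   or \code{"uniform"}
#' @param amplitude amplitude (uM for transient, uM/s for continuous)
#' @param k spike count for the equatorial pattern
#' @param width Gaussian feature width (um)
#' @return a \code{StimulusSpec}
#' @export
stimulusSpec <- function(mode, pattern, amplitude, k = 3L, width = 5)
  new("StimulusSpec", mode = mode, pattern = pattern,
      amplitude = amplitude, k = as.integer(k), width = width)

setMethod("show", "StimulusSpec", function(object)
  cat(sprintf("StimulusSpec: %s %s%s, amplitude %.3g\n", object@mode,
              if (object@pattern == "equatorial")
                paste0(object@k, "-spike ") else "",
              object@pattern, object@amplitude)))

#' Pattern classification outcome
#'
#' @slot nSpikes number of compact activator spikes (0 for none/ring)
#' @slot geometry one of \code{"none"}, \code{"equatorial"}, \code{"polar"},
#'   \code{"tetrahedral"}, \code{"other_spikes"}, \code{"ring"},
#'   \code{"spike_plus_ring"}, \code{"elongated_tetra_edges"},
#'   \code{"failed"}
#' @slot spikeCenters matrix of spike centre positions (rows)
#' @slot metadata list with contrast ratio, component summaries, ...
#' @exportClass PatternLabel
setClass("PatternLabel",
  representation(nSpikes = "integer", geometry = "character",
                 spikeCenters = "matrix", metadata = "list"),
  validity = function(object) {
    ok <- c("none", "equatorial", "polar", "tetrahedral", "other_spikes",
            "ring", "spike_plus_ring", "elongated_tetra_edges", "failed")
    if (!object@geometry %in% ok)
      return(paste("unknown geometry:", object@geometry))
    TRUE
  })

setMethod("show", "PatternLabel", function(object)
  cat(sprintf("PatternLabel: %d spike(s), %s\n", object@nSpikes,
              object@geometry)))

#' Number of spikes of a classified pattern
#' @param object a \code{PatternLabel}
#' @return integer spike count
#' @export
setGeneric("spikeCount", function(object) standardGeneric("spikeCount"))
#' @rdname spikeCount
setMethod("spikeCount", "PatternLabel", function(object) object@nSpikes)

#' Geometry category of a classified pattern
#' @param object a \code{PatternLabel}
#' @return character geometry label
#' @export
setGeneric("patternGeometry",
           function(object) standardGeneric("patternGeometry"))
#' @rdname patternGeometry
setMethod("patternGeometry", "PatternLabel",
          function(object) object@geometry)

#' A synthetic field with its ground-truth label
#' @slot field the generated \code{Field}
#' @slot trueLabel the \code{PatternLabel} the construction encodes
#' @slot generator list of generator settings (template, width, noise, seed)
#' @exportClass LabeledField
setClass("LabeledField",
  representation(field = "Field", trueLabel = "PatternLabel",
                 generator = "list"))

setMethod("show", "LabeledField", function(object) {
  cat("LabeledField with true label: ")
  show(object@trueLabel)
})
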