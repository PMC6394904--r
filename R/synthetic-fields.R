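# geodesic-distance Gaussian template features used by the generator
.geoBump <- function(U, R, center, sigma) {
  th <- acos(pmin(1, pmax(-1, U %*% center)))
  exp(-(R * th / sigma)^2)
}

.geoBand <- function(U, R, normal, sigma) {
  d <- R * asin(pmin(1, abs(U %*% normal)))
  exp(-(d / sigma)^2)
}

# capsule ridge centred at unit vector m, elongated along tangent dir d:
# a Gaussian fall-off of width sigma around a geodesic segment of
# half-length h (tangent-plane log-map coordinates)
.geoRidge <- function(U, R, m, d, h, sigma) {
  th <- as.numeric(acos(pmin(1, pmax(-1, U %*% m))))
  dirs <- U - outer(as.numeric(U %*% m), m)
  dn <- sqrt(rowSums(dirs^2))
  dirs <- dirs / ifelse(dn < 1e-12, 1, dn)
  e2 <- .cross3v(m, d)
  x <- R * th * as.numeric(dirs %*% d)
  y <- R * th * as.numeric(dirs %*% e2)
  dseg <- sqrt(pmax(abs(x) - h, 0)^2 + y^2)
  exp(-(dseg / sigma)^2)
}

.randomRotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.tetraVertices <- function()
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

#' Synthesize a labeled ground-truth field
#'
#' Builds a static activator field of a requested taxonomy class on top of
#' the homogeneous baseline A*: Gaussian bumps, bands or ridges (geodesic
#' distance, widths in um) scaled to a peak height of 4 A*, which clears the
#' classifier's 2 A* contrast gate with margin, plus optional uniform noise
#' expressed as a fraction of the peak height.  Sphere templates are drawn
#' in a uniformly random orientation; the inhibitor is set to H*.  These
#' fields emulate steady-state geometry only, not solver dynamics.
#'
#' @param domain a \code{Domain}
#' @param labelRequest a geometry name (see \code{PatternLabel}) or a list
#'   \code{list(geometry =, k =)}; \code{k} is the spike count where it is
#'   free (equatorial, other_spikes; any k on the ring)
#' @param noiseFraction uniform noise amplitude as a fraction of the 4 A*
#'   peak height
#' @param seed integer seed; the same seed reproduces the same field
#' @param params kinetic parameters supplying the baseline steady state
#' @return a \code{LabeledField}
#' @examples
#' lf <- makeLabeledField(sphereFromFrontArea(550, 2), "tetrahedral",
#'                        seed = 1)
#' patternGeometry(classifyPattern(lf@field))
#' @export
makeLabeledField <- function(domain, labelRequest, noiseFraction = 0,
                             seed = 1L, params = gmParameters()) {
  if (is.character(labelRequest)) labelRequest <- list(geometry = labelRequest)
  geom <- labelRequest$geometry
  k <- labelRequest$k
  if (!is.null(k)) {
    if (geom == "tetrahedral" && k != 4L)
      stop("tetrahedral templates have k = 4 spikes")
    if (geom == "polar" && k != 2L)
      stop("polar templates have k = 2 spikes")
  }
  ss <- steadyState(params)
  peak <- 4 * ss@A
  n <- nNodes(domain)
  set.seed(as.integer(seed))
  if (is(domain, "RingDomain")) {
    if (!geom %in% c("none", "equatorial", "failed"))
      stop(sprintf("ring domain supports none/equatorial/failed, not '%s'",
                   geom))
    if (is.null(k)) k <- 3L
    g <- numeric(n)
    centers <- numeric(0)
    if (geom == "equatorial") {
      offset <- stats::runif(1, 0, domain@length)
      centers <- sort((offset + domain@length * (seq_len(k) - 1) / k) %%
                        domain@length)
      for (cc in centers) {
        d <- abs(domain@positions - cc)
        d <- pmin(d, domain@length - d)
        g <- g + exp(-(d / 3)^2)
      }
    }
    A <- ss@A + peak * g +
      stats::runif(n, -noiseFraction * peak, noiseFraction * peak)
    if (geom == "failed") A[1] <- Inf
    nSpikes <- if (geom == "equatorial") k else 0L
    lab <- new("PatternLabel", nSpikes = as.integer(nSpikes),
               geometry = geom, spikeCenters = matrix(centers, ncol = 1),
               metadata = list(synthetic = TRUE))
    fld <- new("Field", domain = domain, A = A, H = rep(ss@H, n),
               time = NA_real_, ref = c(A = ss@A, H = ss@H),
               meta = list(seed = seed, synthetic = geom))
    return(new("LabeledField", field = fld, trueLabel = lab,
               generator = list(geometry = geom, k = k, peak = peak,
                                noiseFraction = noiseFraction, seed = seed)))
  }
  R <- domain@radius
  U <- domain@vertices / R
  Q <- .randomRotation()
  rot <- function(M) M %*% Q          # rows are unit vectors
  sigma <- 2.5
  g <- numeric(n)
  centers <- matrix(numeric(0), 0, 3)
  nSpikes <- 0L
  equator <- function(kk) {
    th <- 2 * pi * (seq_len(kk) - 1) / kk
    cbind(cos(th), 0, sin(th))
  }
  addBumps <- function(C) {
    for (i in seq_len(nrow(C))) g <<- g + .geoBump(U, R, C[i, ], sigma)
    centers <<- rbind(centers, C * R)
    nSpikes <<- nSpikes + nrow(C)
  }
  poleY <- rot(matrix(c(0, 1, 0), 1))[1, ]
  switch(geom,
    none = NULL,
    failed = NULL,
    equatorial = {
      if (is.null(k)) k <- 3L
      if (k < 3L) stop("equatorial sphere templates need k >= 3")
      addBumps(rot(equator(k)))
    },
    polar = addBumps(rot(rbind(c(0, 1, 0), c(0, -1, 0)))),
    tetrahedral = addBumps(rot(.tetraVertices())),
    other_spikes = {
      if (is.null(k)) k <- 5L
      base <- rbind(equator(3),
                    c(cos(pi / 3) * cos(pi / 4), sin(pi / 3),
                      cos(pi / 3) * sin(pi / 4)),
                    c(-cos(pi / 3) * cos(pi / 8), -sin(pi / 3),
                      -cos(pi / 3) * sin(pi / 8)))
      addBumps(rot(base[seq_len(min(k, 5L)), , drop = FALSE]))
    },
    ring = g <- .geoBand(U, R, poleY, sigma),
    spike_plus_ring = {
      g <- .geoBand(U, R, poleY, sigma)
      addBumps(matrix(poleY, 1))
    },
    elongated_tetra_edges = {
      tv <- rot(.tetraVertices())
      pairs <- utils::combn(4, 2)
      for (e in seq_len(ncol(pairs))) {
        vi <- tv[pairs[1, e], ]; vj <- tv[pairs[2, e], ]
        m <- .unit(vi + vj)
        d <- .unit(vj - vi - sum((vj - vi) * m) * m)
        halfEdge <- R * 1.9106 / 2   # half the tetra edge arc length
        g <- g + .geoRidge(U, R, m, d, h = 0.5 * halfEdge, sigma = 2)
        centers <- rbind(centers, m * R)
      }
      nSpikes <- 6L
    },
    stop(sprintf("unknown label request '%s'", geom)))
  if (geom %in% c("ring", "spike_plus_ring") && is.null(k)) k <- 0L
  A <- ss@A + peak * g +
    stats::runif(n, -noiseFraction * peak, noiseFraction * peak)
  if (geom == "failed") A[1] <- Inf
  lab <- new("PatternLabel", nSpikes = nSpikes, geometry = geom,
             spikeCenters = centers, metadata = list(synthetic = TRUE))
  fld <- new("Field", domain = domain, A = A, H = rep(ss@H, n),
             time = NA_real_, ref = c(A = ss@A, H = ss@H),
             meta = list(seed = seed, synthetic = geom))
  new("LabeledField", field = fld, trueLabel = lab,
      generator = list(geometry = geom, k = k, peak = peak,
                       sigma = sigma, noiseFraction = noiseFraction,
                       seed = seed))
}

#' Deterministic fixture suite covering the whole taxonomy
#'
#' Generates at least \code{perClass} labeled fields for every sphere
#' taxonomy class, split across the wild-type (550 um^2) and larger
#' (750 um^2) domain sizes, in random orientations derived from
#' \code{seed}.  The suite is the classifier's validation surface: on the
#' clean suite (zero noise) classification must recover every true label.
#'
#' @param seed integer seed
#' @param perClass fields per taxonomy class (>= 20 by default)
#' @param noiseFraction uniform noise fraction passed through
#' @param level icosphere subdivision level
#' @return list of \code{LabeledField}
#' @export
fixtureSuite <- function(seed = 1L, perClass = 20L, noiseFraction = 0,
                         level = 3L) {
  domains <- list(sphereFromFrontArea(550, level),
                  sphereFromFrontArea(750, level))
  classes <- list(
    list(geometry = "none"), list(geometry = "failed"),
    list(geometry = "equatorial", k = 3L),
    list(geometry = "equatorial", k = 4L),
    list(geometry = "polar"), list(geometry = "tetrahedral"),
    list(geometry = "other_spikes", k = 5L),
    list(geometry = "ring"), list(geometry = "spike_plus_ring"),
    list(geometry = "elongated_tetra_edges"))
  out <- list()
  i <- 0L
  for (cl in classes) for (j in seq_len(perClass)) {
    i <- i + 1L
    dom <- domains[[1L + (j %% 2L)]]
    out[[i]] <- makeLabeledField(dom, cl, noiseFraction,
                                 seed = as.integer(seed) * 10000L + i)
  }
  out
}
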