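#' Classifier tuning constants
#'
#' The thresholds that operationalize the visual pattern taxonomy.  Values
#' are dimensionless or in degrees; all are explicit here so their
#' sensitivity can be probed.
#'
#' @param thresholdFrac super-threshold cut as a fraction of max(A)
#' @param contrastHigh pattern gate: max(A) must exceed this multiple of A*
#'   (a homogeneous field sits at 1.0 A*; patterned spikes reach well above 2 A*)
#' @param contrastRange pattern gate: the peak-to-valley range max(A) - min(A)
#'   must exceed this multiple of A*, so uniformly elevated fields stay
#'   unpatterned
#' @param ringExtentDeg great-circle angular coverage (degrees) above which a
#'   component is a ring
#' @param elongAspect major/minor extent ratio above which a compact
#'   component counts as elongated
#' @param angleTolDeg angular tolerance (degrees) for the tetrahedral and
#'   coplanarity tests
#' @param polarMinDeg minimum separation (degrees) for a two-spike pattern
#'   to be called polar/opposite
#' @return named list of constants
#' @export
classifyControl <- function(thresholdFrac = 0.5, contrastHigh = 1.5,
                            contrastRange = 1, ringExtentDeg = 300,
                            elongAspect = 3, angleTolDeg = 15,
                            polarMinDeg = 150)
  list(thresholdFrac = thresholdFrac, contrastHigh = contrastHigh,
       contrastRange = contrastRange, ringExtentDeg = ringExtentDeg,
       elongAspect = elongAspect, angleTolDeg = angleTolDeg,
       polarMinDeg = polarMinDeg)

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(NA_real_, NA_real_, NA_real_))
  v / n
}

.angleDeg <- function(u, v)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi

# best-fit plane through the origin for rows of unit-vector matrix U:
# normal, max angular deviation from the plane (deg), and angular coverage
# of the azimuths around the plane (deg)
.planeStats <- function(U, w = rep(1, nrow(U))) {
  M <- crossprod(U * sqrt(w))
  e <- eigen(M, symmetric = TRUE)
  nrm <- e$vectors[, 3]
  dev <- asin(pmin(1, abs(U %*% nrm))) * 180 / pi
  e1 <- .unit(e$vectors[, 1])
  e2 <- .unit(.cross3v(nrm, e1))
  az <- atan2(U %*% e2, U %*% e1)
  az <- sort(as.numeric(az))
  gaps <- diff(c(az, az[1] + 2 * pi))
  coverage <- 360 - max(gaps) * 180 / pi
  list(normal = nrm, maxDev = max(dev), coverage = coverage)
}

.cross3v <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Super-threshold connected components of an activator field
#'
#' Thresholds the activator at \code{thresholdFrac} of its maximum and
#' extracts connected components on the sphere mesh adjacency.  Each
#' component is summarized by its nodes, mass-weighted centroid direction,
#' surface area, angular coverage around its best-fit great circle, and
#' principal tangent-plane extents (used for the elongation test).
#'
#' @param field a \code{Field} on a \code{SphereDomain}
#' @param control constants from \code{\link{classifyControl}}
#' @return list of component summaries
#' @export
findComponents <- function(field, control = classifyControl()) {
  domain <- field@domain
  stopifnot(is(domain, "SphereDomain"))
  A <- field@A
  thr <- control$thresholdFrac * max(A)
  mask <- which(A >= thr)
  f <- domain@faces
  edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  keep <- edges[, 1] %in% mask & edges[, 2] %in% mask
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges[keep, , drop = FALSE]), ncol = 2),
    directed = FALSE)
  g <- igraph::add_vertices(g,
    sum(!as.character(mask) %in% igraph::V(g)$name),
    name = setdiff(as.character(mask), igraph::V(g)$name))
  comp <- igraph::components(g)
  R <- domain@radius
  U <- domain@vertices / R
  lapply(seq_len(comp$no), function(ci) {
    nodes <- as.integer(igraph::V(g)$name[comp$membership == ci])
    w <- domain@mass[nodes]
    u <- U[nodes, , drop = FALSE]
    cen <- .unit(colSums(u * w))
    ps <- .planeStats(u, w)
    if (length(nodes) >= 3 && !any(is.na(cen))) {
      t1 <- .unit(if (abs(cen[1]) < 0.9) .cross3v(cen, c(1, 0, 0))
                  else .cross3v(cen, c(0, 1, 0)))
      t2 <- .cross3v(cen, t1)
      th <- acos(pmin(1, pmax(-1, u %*% cen)))
      dirs <- u - outer(as.numeric(u %*% cen), cen)
      dn <- sqrt(rowSums(dirs^2))
      dirs <- dirs / ifelse(dn < 1e-12, 1, dn)
      x <- R * th * (dirs %*% t1)
      y <- R * th * (dirs %*% t2)
      cv <- stats::cov.wt(cbind(as.numeric(x), as.numeric(y)), wt = w)$cov
      ev <- eigen(cv, symmetric = TRUE)
      proj <- cbind(as.numeric(x), as.numeric(y)) %*% ev$vectors
      major <- diff(range(proj[, 1]))
      minor <- diff(range(proj[, 2]))
    } else major <- minor <- 0
    list(nodes = nodes, centroid = cen, area = sum(w),
         coverage = ps$coverage, planeNormal = ps$normal,
         major = major, minor = minor,
         aspect = if (minor > 1e-9) major / minor else 1)
  })
}

.labelFailed <- function()
  new("PatternLabel", nSpikes = 0L, geometry = "failed",
      spikeCenters = matrix(numeric(0), 0, 3),
      metadata = list(diverged = TRUE))

.labelNone <- function(meta = list())
  new("PatternLabel", nSpikes = 0L, geometry = "none",
      spikeCenters = matrix(numeric(0), 0, 3), metadata = meta)

#' Count activator spikes on the ring
#'
#' Number of contiguous runs of nodes above \code{thresholdFrac} of max(A),
#' with periodic wraparound (a run crossing the origin is one spike) --
#' adjacent maxima sharing one super-threshold plateau merge into a single
#' spike.  An unpatterned field (contrast gate not passed) counts zero.
#'
#' @param field a \code{Field} on a \code{RingDomain}
#' @param control constants from \code{\link{classifyControl}}
#' @return integer spike count, with attribute \code{"centers"} giving the
#'   arc-length positions of the within-run activator maxima
#' @export
countSpikesRing <- function(field, control = classifyControl()) {
  stopifnot(is(field@domain, "RingDomain"))
  A <- field@A
  if (!all(is.finite(A))) return(structure(0L, centers = numeric(0)))
  Astar <- field@ref[["A"]]
  if (max(A) < control$contrastHigh * Astar ||
      max(A) - min(A) < control$contrastRange * Astar)
    return(structure(0L, centers = numeric(0)))
  mask <- A >= control$thresholdFrac * max(A)
  r <- rle(mask)
  runs <- which(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runIdx <- lapply(runs, function(i) starts[i]:ends[i])
  # periodic wraparound: merge a run touching the end with one at the start
  if (length(runIdx) > 1L && mask[1L] && mask[length(mask)]) {
    runIdx[[1L]] <- c(runIdx[[length(runIdx)]], runIdx[[1L]])
    runIdx[[length(runIdx)]] <- NULL
  }
  centers <- vapply(runIdx, function(ix)
    field@domain@positions[ix[which.max(A[ix])]], numeric(1))
  structure(length(runIdx), centers = sort(centers))
}

#' Classify a steady-state activator field
#'
#' Maps a steady-state field onto the spike-pattern taxonomy.  The decision
#' cascade: (i) fields failing the contrast gate (peak below
#' \code{contrastHigh} A* or peak-to-valley range below
#' \code{contrastRange} A*) are unpatterned ("none"); (ii) a super-threshold
#' component whose best-fit great circle is covered over >= 300 degrees is a
#' ring -- one ring alone gives "ring", a ring plus one compact spike
#' "spike_plus_ring"; (iii) six elongated components (major/minor extent
#' >= 3) give "elongated_tetra_edges"; (iv) otherwise compact components are
#' counted as spikes: four spikes are "tetrahedral" when all pairwise centre
#' angles are within 15 degrees of 109.47 degrees, spikes coplanar with the
#' sphere centre (within 15 degrees) are "equatorial", two spikes separated
#' by >= 150 degrees (or a single spike) are "polar", anything else
#' "other_spikes".  Non-finite inputs give "failed".  On a ring domain the
#' spike count comes from \code{\link{countSpikesRing}}.
#'
#' @param field a steady-state \code{Field}
#' @param control constants from \code{\link{classifyControl}}
#' @return a \code{PatternLabel}
#' @export
classifyPattern <- function(field, control = classifyControl()) {
  A <- field@A
  if (!all(is.finite(A)) || !all(is.finite(field@H)))
    return(.labelFailed())
  Astar <- field@ref[["A"]]
  contrast <- max(A) / Astar
  if (is(field@domain, "RingDomain")) {
    n <- countSpikesRing(field, control)
    centers <- attr(n, "centers")
    geom <- if (n == 0L) "none" else "equatorial"
    return(new("PatternLabel", nSpikes = as.integer(n), geometry = geom,
               spikeCenters = matrix(centers, ncol = 1),
               metadata = list(contrast = contrast)))
  }
  if (max(A) < control$contrastHigh * Astar ||
      max(A) - min(A) < control$contrastRange * Astar)
    return(.labelNone(list(contrast = contrast)))
  comps <- findComponents(field, control)
  isRing <- vapply(comps, function(cc) cc$coverage >= control$ringExtentDeg,
                   logical(1))
  rings <- comps[isRing]
  compact <- comps[!isRing]
  R <- field@domain@radius
  centers <- do.call(rbind, lapply(compact, function(cc) cc$centroid * R))
  if (is.null(centers)) centers <- matrix(numeric(0), 0, 3)
  meta <- list(contrast = contrast, nComponents = length(comps),
               nRings = length(rings),
               coverage = vapply(comps, `[[`, numeric(1), "coverage"),
               aspect = vapply(comps, `[[`, numeric(1), "aspect"))
  mk <- function(n, geom) new("PatternLabel", nSpikes = as.integer(n),
                              geometry = geom, spikeCenters = centers,
                              metadata = meta)
  if (length(rings) >= 1L) {
    if (length(compact) == 0L && length(rings) == 1L) return(mk(0, "ring"))
    if (length(compact) == 1L && length(rings) == 1L)
      return(mk(1, "spike_plus_ring"))
    return(mk(length(compact), "other_spikes"))
  }
  nElong <- sum(vapply(compact, function(cc)
    cc$aspect >= control$elongAspect, logical(1)))
  if (nElong == 6L && length(compact) == 6L)
    return(mk(6, "elongated_tetra_edges"))
  k <- length(compact)
  if (k == 0L) return(.labelNone(meta))
  u <- centers / R
  tol <- control$angleTolDeg
  if (k == 1L) return(mk(1, "polar"))
  pair <- utils::combn(k, 2)
  angles <- apply(pair, 2, function(ij) .angleDeg(u[ij[1], ], u[ij[2], ]))
  if (k == 2L)
    return(mk(2, if (angles[1] >= control$polarMinDeg) "polar"
                 else "equatorial"))
  if (k == 4L && all(abs(angles - 109.4712) <= tol))
    return(mk(4, "tetrahedral"))
  ps <- .planeStats(u)
  if (ps$maxDev <= tol) return(mk(k, "equatorial"))
  mk(k, "other_spikes")
}
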