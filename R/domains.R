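#' Build a periodic ring domain from a front-view area
#'
#' The ring represents the equator of a microspore whose projected
#' (front-view) area is \code{area} = pi R^2; its length is the full
#' equatorial circumference 2 pi R = 2 sqrt(pi area), discretized with
#' uniformly spaced nodes and periodic topology.
#'
#' @param area front-view area (um^2)
#' @param nNodes number of grid nodes (default 256)
#' @return a \code{RingDomain}
#' @examples
#' ringFromFrontArea(550)
#' @export
ringFromFrontArea <- function(area, nNodes = 256L) {
  if (area <= 0) stop("area must be positive")
  nNodes <- as.integer(nNodes)
  radius <- sqrt(area / pi)
  len <- 2 * pi * radius
  new("RingDomain", frontArea = area, radius = radius, length = len,
      nNodes = nNodes, positions = seq(0, len, length.out = nNodes + 1L)[-(nNodes + 1L)])
}

# icosahedron vertices/faces used as the subdivision base
.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7),
             c(8, 2, 9), c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9),
             c(4, 9, 10), c(5, 10, 6), c(3, 5, 12), c(7, 3, 11),
             c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

.subdivide <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  midCache <- new.env(hash = TRUE)
  nv <- nrow(v)
  verts <- vector("list", nrow(f) * 3L)
  vlist <- list(v)
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    idx <- midCache[[key]]
    if (!is.null(idx)) return(idx)
    m <- (v[i, ] + v[j, ]) / 2
    m <- m / sqrt(sum(m^2))
    nv <<- nv + 1L
    vlist[[length(vlist) + 1L]] <<- m
    midCache[[key]] <- nv
    nv
  }
  newf <- matrix(0L, nrow(f) * 4L, 3L)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newf[4 * t - 3, ] <- c(a, ab, ca)
    newf[4 * t - 2, ] <- c(b, bc, ab)
    newf[4 * t - 1, ] <- c(c, ca, bc)
    newf[4 * t, ] <- c(ab, bc, ca)
  }
  list(vertices = do.call(rbind, vlist), faces = newf)
}

# cotangent-weight stiffness matrix and lumped barycentric vertex areas
.cotanLaplacian <- function(vertices, faces) {
  n <- nrow(vertices)
  nf <- nrow(faces)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  mass <- numeric(n)
  cross3 <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  p1 <- vertices[faces[, 1], , drop = FALSE]
  p2 <- vertices[faces[, 2], , drop = FALSE]
  p3 <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3(p2 - p1, p3 - p1)
  area2 <- sqrt(rowSums(cr^2))          # 2 * triangle area
  farea <- area2 / 2
  for (k in 1:3) {
    tab <- tapply(farea / 3, faces[, k], sum)
    idx <- as.integer(names(tab))
    mass[idx] <- mass[idx] + tab
  }
  # cot of angle at vertex k of each face, opposite edge (i,j)
  cot <- function(pa, pb, pc) {
    u <- pb - pa; v <- pc - pa
    rowSums(u * v) / area2
  }
  c1 <- cot(p1, p2, p3)  # angle at vertex 1, opposite edge (2,3)
  c2 <- cot(p2, p3, p1)
  c3 <- cot(p3, p1, p2)
  ii <- c(faces[, 2], faces[, 3], faces[, 1])
  jj <- c(faces[, 3], faces[, 1], faces[, 2])
  ww <- c(c1, c2, c3) / 2
  L <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  d <- Matrix::Diagonal(x = as.numeric(Matrix::rowSums(L)))
  list(L = L - d, mass = mass)
}

#' Build a sphere-surface domain from a front-view area
#'
#' The microspore surface is modeled as a perfect sphere of radius
#' R = sqrt(area/pi), triangulated by subdividing an icosahedron
#' \code{level} times and projecting to the sphere.  The discrete
#' Laplace-Beltrami operator uses cotangent edge weights with a lumped
#' barycentric mass matrix.  The y axis is the polar axis; the y = 0 plane
#' is the equator.
#'
#' @param area front-view area (um^2); the full sphere surface is 4x this
#' @param level icosphere subdivision level (default 3: 642 vertices)
#' @return a \code{SphereDomain}
#' @examples
#' sphereFromFrontArea(550, level = 2)
#' @export
sphereFromFrontArea <- function(area, level = 3L) {
  if (area <= 0) stop("area must be positive")
  level <- as.integer(level)
  mesh <- .icosahedron()
  for (i in seq_len(level)) mesh <- .subdivide(mesh)
  radius <- sqrt(area / pi)
  vertices <- mesh$vertices * radius
  lap <- .cotanLaplacian(vertices, mesh$faces)
  new("SphereDomain", frontArea = area, radius = radius, level = level,
      vertices = vertices, faces = mesh$faces, laplacian = lap$L,
      mass = lap$mass)
}

#' Apply the discrete Laplacian of a domain to a field
#'
#' Second spatial derivative per node: spectral (Fourier) differentiation on
#' the periodic ring, and the cotangent-weight Laplace-Beltrami operator
#' (stiffness over lumped mass) on the sphere.  A constant field maps to
#' zero, and eigenfunctions reproduce their analytic eigenvalues
#' -(2 pi m / L)^2 (ring) and -l(l+1)/R^2 (sphere) within discretization
#' tolerance.
#'
#' @param domain a \code{Domain}
#' @param values numeric field with one value per node
#' @return numeric vector, units value/um^2
#' @export
applyLaplacian <- function(domain, values) {
  if (length(values) != nNodes(domain))
    stop(sprintf("field length %d does not match node count %d",
                 length(values), nNodes(domain)))
  if (is(domain, "RingDomain")) {
    n <- domain@nNodes
    k <- 2 * pi / domain@length *
      c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    Re(stats::fft(stats::fft(values) * (-k^2), inverse = TRUE)) / n
  } else {
    as.numeric(domain@laplacian %*% values) / domain@mass
  }
}

#' Spatial modes inside the unstable Turing band
#'
#' Counts the discrete modes whose squared wavenumber falls in the unstable
#' band of a \code{TuringReport}: integer wavenumbers m with
#' (2 pi m / L)^2 in the band on the ring, and spherical-harmonic degrees l
#' with l(l+1)/R^2 in the band on the sphere.
#'
#' @param domain a \code{Domain}
#' @param turing a satisfied \code{TuringReport}
#' @return integer vector of admissible mode numbers (possibly empty)
#' @export
admissibleModes <- function(domain, turing) {
  if (!isTRUE(turing@satisfied)) return(integer(0))
  if (is(domain, "RingDomain")) {
    m <- seq_len(2 * domain@nNodes)
    k2 <- (2 * pi * m / domain@length)^2
  } else {
    m <- seq_len(1000L)
    k2 <- m * (m + 1) / domain@radius^2
  }
  m[k2 > turing@k2Minus & k2 < turing@k2Plus]
}

#' Export a sphere mesh as a Wavefront OBJ file
#' @param domain a \code{SphereDomain}
#' @param path output file path
#' @param values optional per-node scalar written as a comment table
#' @return invisibly, the path
#' @export
writeOBJ <- function(domain, path, values = NULL) {
  stopifnot(is(domain, "SphereDomain"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# icosphere mesh export", con)
  writeLines(sprintf("v %.8g %.8g %.8g", domain@vertices[, 1],
                     domain@vertices[, 2], domain@vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", domain@faces[, 1], domain@faces[, 2],
                     domain@faces[, 3]), con)
  if (!is.null(values))
    writeLines(sprintf("# value %d %.8g", seq_along(values), values), con)
  invisible(path)
}
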