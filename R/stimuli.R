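#' Gaussian stimulus bump on the sphere
#'
#' Per node at position (x, y, z), the stimulus value is
#' \code{amplitude * exp(-((x-x0)^2 + (y-y0)^2 + (z-z0)^2))}: a Gaussian in
#' Euclidean (chord) distance from the centre with unit length scale (1 um),
#' so the value drops to amplitude/e one micron from the centre.
#'
#' @param domain a \code{SphereDomain}
#' @param center length-3 centre position on the sphere surface (um)
#' @param amplitude peak value at the centre
#' @param width Gaussian width (um); the printed stimulus equation is the
#'   unit-width special case
#' @return numeric per-node stimulus field
#' @export
gaussianBump <- function(domain, center, amplitude = 1, width = 1) {
  stopifnot(is(domain, "SphereDomain"), length(center) == 3)
  d2 <- rowSums(sweep(domain@vertices, 2, center)^2)
  amplitude * exp(-d2 / width^2)
}

#' Centre points of a stimulus pattern
#'
#' k-spike equatorial patterns place k points equally spaced on the equator
#' (the y = 0 great circle); the tetrahedral pattern uses the vertices of a
#' regular tetrahedron inscribed in the sphere.
#'
#' @param domain a \code{SphereDomain}
#' @param spec a \code{StimulusSpec}
#' @return matrix of centre positions (rows), or a 0-row matrix for the
#'   ring and uniform patterns
#' @export
stimulusCenters <- function(domain, spec) {
  R <- domain@radius
  switch(spec@pattern,
    equatorial = {
      th <- 2 * pi * (seq_len(spec@k) - 1) / spec@k
      cbind(R * cos(th), 0, R * sin(th))
    },
    tetrahedral = R * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                            c(-1, -1, 1)) / sqrt(3),
    matrix(numeric(0), 0, 3))
}

#' Build a stimulus field on the sphere
#'
#' Sums Gaussian bumps of the spec's width at the pattern's centre points;
#' the ring pattern is \code{amplitude * exp(-(y/width)^2)} (a band around
#' the equator, y being the polar-axis coordinate in um); the uniform
#' pattern adds the same value everywhere.  The default width makes the
#' stimuli resemble the spike patterns the model itself produces.
#'
#' @param domain a \code{SphereDomain}
#' @param spec a \code{StimulusSpec}
#' @return numeric per-node stimulus field (non-negative)
#' @export
buildStimulus <- function(domain, spec) {
  stopifnot(is(domain, "SphereDomain"), is(spec, "StimulusSpec"))
  switch(spec@pattern,
    ring = spec@amplitude * exp(-(domain@vertices[, 2] / spec@width)^2),
    uniform = rep(spec@amplitude, nNodes(domain)),
    {
      centers <- stimulusCenters(domain, spec)
      f <- numeric(nNodes(domain))
      for (i in seq_len(nrow(centers)))
        f <- f + gaussianBump(domain, centers[i, ], spec@amplitude,
                              spec@width)
      f
    })
}
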