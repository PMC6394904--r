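#' Derive a replicate seed from campaign coordinates
#'
#' Each replicate gets its own pseudo-random stream, deterministically
#' derived from the campaign base seed, the condition index and the
#' replicate index, so campaigns are reproducible row by row.
#'
#' @param baseSeed campaign base seed (integer)
#' @param condition condition index (1-based)
#' @param replicate replicate index (1-based)
#' @return a positive integer seed below 2^31
#' @export
replicateSeed <- function(baseSeed, condition, replicate)
  as.integer((as.numeric(baseSeed) * 1000003 + condition * 10007 +
                replicate * 101) %% 2147483629) + 1L

.labelString <- function(label) {
  g <- label@geometry
  if (g %in% c("none", "ring", "failed")) g
  else paste0(label@nSpikes, "-", g)
}

.campaignRow <- function(domainType, area, parameterName, factor,
                         stimulus, replicate, seed, run) {
  lab <- run$label
  res <- run$result
  data.frame(domain_type = domainType, front_area = area,
             parameter_name = parameterName, scale_factor = factor,
             stimulus_mode = if (is.null(stimulus)) NA_character_
                             else stimulus@mode,
             stimulus_pattern = if (is.null(stimulus)) NA_character_
                                else stimulus@pattern,
             stimulus_amplitude = if (is.null(stimulus)) NA_real_
                                  else stimulus@amplitude,
             replicate = replicate, seed = seed,
             label = .labelString(lab), geometry = lab@geometry,
             n_spikes = lab@nSpikes, converged = res@converged,
             diverged = res@diverged, model_time = res@elapsedModelTime,
             stim_min_dist = .stimDistance(lab, stimulus,
                                           res@final@domain),
             stringsAsFactors = FALSE)
}

# geodesic distance (um) from the nearest resulting spike centre to the
# nearest stimulus centre; NA when either side has no centres
.stimDistance <- function(label, stimulus, domain) {
  if (is.null(stimulus) || !is(domain, "SphereDomain")) return(NA_real_)
  sc <- stimulusCenters(domain, stimulus)
  pc <- label@spikeCenters
  if (nrow(sc) == 0L || is.null(pc) || nrow(pc) == 0L ||
      ncol(pc) != 3L) return(NA_real_)
  R <- domain@radius
  d <- outer(seq_len(nrow(pc)), seq_len(nrow(sc)), Vectorize(function(i, j)
    R * acos(max(-1, min(1, sum(pc[i, ] * sc[j, ]) / R^2)))))
  min(d)
}

.makeDomain <- function(domainType, area, nNodes, level) {
  if (domainType == "ring") ringFromFrontArea(area, nNodes)
  else sphereFromFrontArea(area, level)
}

.finishCampaign <- function(rows, manifest) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- manifest
  out
}

#' Domain-size sweep
#'
#' Runs the base parameterization on a series of domain sizes (front-view
#' areas) with independently seeded replicates and tabulates the resulting
#' pattern labels.  The full study sweeps 250 to 1450 um^2 in 50 um^2
#' steps with 25 replicates per area; diverged replicates are recorded as
#' "failed" rows, never aborting the campaign.
#'
#' @param domainType \code{"ring"} or \code{"sphere"}
#' @param areas front-view areas (um^2)
#' @param reps replicates per area
#' @param baseSeed campaign base seed
#' @param params kinetic parameters
#' @param config a \code{SimConfig} template (per-replicate seeds are
#'   derived internally)
#' @param nNodes ring resolution
#' @param level sphere resolution
#' @return long-form \code{data.frame}, one row per replicate, with a
#'   \code{"manifest"} attribute recording all settings
#' @export
domainSizeSweep <- function(domainType = c("ring", "sphere"),
                            areas = seq(250, 1450, by = 50), reps = 25L,
                            baseSeed = 1L, params = gmParameters(),
                            config = simConfig(), nNodes = 256L,
                            level = 3L) {
  domainType <- match.arg(domainType)
  rows <- list()
  for (ci in seq_along(areas)) {
    domain <- .makeDomain(domainType, areas[ci], nNodes, level)
    for (ri in seq_len(reps)) {
      sd <- replicateSeed(baseSeed, ci, ri)
      cfg <- config; cfg@seed <- sd
      run <- runOne(params, domain, cfg)
      rows[[length(rows) + 1L]] <-
        .campaignRow(domainType, areas[ci], NA_character_, NA_real_,
                     NULL, ri, sd, run)
    }
  }
  .finishCampaign(rows, list(campaign = "domain_size",
                             domain_type = domainType, areas = areas,
                             reps = reps, base_seed = baseSeed,
                             params = .paramsList(params),
                             nNodes = nNodes, level = level))
}

#' One-parameter-at-a-time kinetics sweep
#'
#' Scales a single kinetic parameter over a factor grid (default 20% to
#' 300% in 20% steps; \code{"rho"} scales both reaction efficiencies
#' jointly) on the requested domain sizes, running seeded replicates per
#' factor and tabulating labels.
#'
#' @param parameterName one of D_A, D_H, mu_A, mu_H, rho, rho_A, rho_H
#' @param domainType \code{"ring"} or \code{"sphere"}
#' @param areas front-view areas, default wild-type and larger domains
#' @param factors multiplicative factors applied to the parameter
#' @param reps replicates per (area, factor)
#' @param baseSeed campaign base seed
#' @param params base kinetic parameters
#' @param config a \code{SimConfig} template
#' @param nNodes ring resolution
#' @param level sphere resolution
#' @return long-form \code{data.frame} as in \code{\link{domainSizeSweep}}
#' @export
oatKineticsSweep <- function(parameterName,
                             domainType = c("ring", "sphere"),
                             areas = c(550, 750),
                             factors = seq(0.2, 3, by = 0.2), reps = 25L,
                             baseSeed = 1L, params = gmParameters(),
                             config = simConfig(), nNodes = 256L,
                             level = 3L) {
  domainType <- match.arg(domainType)
  stopifnot(parameterName %in% c(gmParameterNames(), "rho"))
  rows <- list()
  ci <- 0L
  for (area in areas) {
    domain <- .makeDomain(domainType, area, nNodes, level)
    for (f in factors) {
      ci <- ci + 1L
      p <- scaleParameter(params, parameterName, f)
      for (ri in seq_len(reps)) {
        sd <- replicateSeed(baseSeed, ci, ri)
        cfg <- config; cfg@seed <- sd
        run <- runOne(p, domain, cfg)
        rows[[length(rows) + 1L]] <-
          .campaignRow(domainType, area, parameterName, f, NULL, ri, sd,
                       run)
      }
    }
  }
  .finishCampaign(rows, list(campaign = "oat_kinetics",
                             parameter = parameterName,
                             domain_type = domainType, areas = areas,
                             factors = factors, reps = reps,
                             base_seed = baseSeed,
                             params = .paramsList(params),
                             nNodes = nNodes, level = level))
}

#' Stimulus campaign on the sphere
#'
#' Applies a transient or continuous stimulus of a given pattern over an
#' amplitude grid and domain sizes, running seeded replicates per
#' condition.  Rows record, besides the label, the geodesic distance from
#' the nearest resulting spike to the nearest stimulus centre, so the
#' positional-influence property (a stimulated pattern keeps at least one
#' spike at a stimulus position) can be tabulated.
#'
#' @param mode \code{"transient"} or \code{"continuous"}
#' @param pattern stimulus pattern (see \code{\link{stimulusSpec}})
#' @param amplitudes amplitude grid (uM for transient, uM/s continuous)
#' @param domainAreas sphere front-view areas (um^2)
#' @param reps replicates per condition
#' @param baseSeed campaign base seed
#' @param k spike count for equatorial stimulus patterns
#' @param params kinetic parameters
#' @param config a \code{SimConfig} template
#' @param level sphere resolution
#' @return long-form \code{data.frame} as in \code{\link{domainSizeSweep}}
#' @export
stimulusCampaign <- function(mode, pattern, amplitudes,
                             domainAreas = c(550, 750), reps = 5L,
                             baseSeed = 1L, k = 3L,
                             params = gmParameters(),
                             config = simConfig(), level = 3L) {
  rows <- list()
  ci <- 0L
  for (area in domainAreas) {
    domain <- sphereFromFrontArea(area, level)
    for (amp in amplitudes) {
      ci <- ci + 1L
      spec <- stimulusSpec(mode, pattern, amp, k)
      for (ri in seq_len(reps)) {
        sd <- replicateSeed(baseSeed, ci, ri)
        cfg <- config; cfg@seed <- sd
        run <- runOne(params, domain, cfg, spec)
        rows[[length(rows) + 1L]] <-
          .campaignRow("sphere", area, NA_character_, NA_real_, spec, ri,
                       sd, run)
      }
    }
  }
  .finishCampaign(rows, list(campaign = "stimulus", mode = mode,
                             pattern = pattern, k = k,
                             amplitudes = amplitudes,
                             areas = domainAreas, reps = reps,
                             base_seed = baseSeed,
                             params = .paramsList(params), level = level))
}

#' Per-condition label frequency table
#'
#' Collapses a campaign table into label frequencies per condition
#' (domain type, area, scaled parameter, stimulus).  Frequencies sum to
#' the number of replicates of each condition; failed runs appear as their
#' own label category.
#'
#' @param result a campaign \code{data.frame}
#' @return \code{data.frame} with one row per (condition, label) and
#'   columns \code{count} and \code{freq}
#' @export
summarizeCampaign <- function(result) {
  if (nrow(result) == 0L)
    return(data.frame(front_area = numeric(0), label = character(0),
                      count = integer(0), freq = numeric(0)))
  condCols <- c("domain_type", "front_area", "parameter_name",
                "scale_factor", "stimulus_mode", "stimulus_pattern",
                "stimulus_amplitude")
  key <- do.call(paste, c(result[condCols], sep = "\r"))
  tab <- as.data.frame(table(key = key, label = result$label),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  parts <- do.call(rbind, strsplit(tab$key, "\r", fixed = TRUE))
  out <- data.frame(parts, label = tab$label, count = tab$Freq,
                    stringsAsFactors = FALSE)
  names(out)[seq_along(condCols)] <- condCols
  out$front_area <- as.numeric(out$front_area)
  out$scale_factor <- suppressWarnings(as.numeric(out$scale_factor))
  out$stimulus_amplitude <-
    suppressWarnings(as.numeric(out$stimulus_amplitude))
  reps <- stats::ave(out$count, do.call(paste, out[condCols]),
                     FUN = sum)
  out$freq <- out$count / reps
  rownames(out) <- NULL
  out[order(out$domain_type, out$front_area, out$label), ]
}
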