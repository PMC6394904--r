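#' Run configuration
#'
#' Bundles everything one simulation needs: kinetic parameters, a domain
#' specification, simulation settings and an optional stimulus.  Defaults
#' reproduce the wild-type setup: base parameters, a 550 um^2 domain and
#' 5e-4 uM initial-condition noise.
#'
#' @slot params a \code{GMParameters}
#' @slot domainType \code{"ring"} or \code{"sphere"}
#' @slot domainArea front-view area (um^2)
#' @slot nNodes ring resolution
#' @slot level sphere resolution
#' @slot sim a \code{SimConfig}
#' @slot stimulus a \code{StimulusSpec} or \code{NULL}
#' @exportClass RunConfig
setClass("RunConfig",
  representation(params = "GMParameters", domainType = "character",
                 domainArea = "numeric", nNodes = "integer",
                 level = "integer", sim = "SimConfig", stimulus = "ANY"))

#' Construct a run configuration
#' @param params,domainType,domainArea,nNodes,level,sim,stimulus see the
#'   class slots
#' @return a \code{RunConfig}
#' @export
runConfig <- function(params = gmParameters(), domainType = "ring",
                      domainArea = 550, nNodes = 256L, level = 3L,
                      sim = simConfig(), stimulus = NULL)
  new("RunConfig", params = params, domainType = domainType,
      domainArea = domainArea, nNodes = as.integer(nNodes),
      level = as.integer(level), sim = sim, stimulus = stimulus)

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: %s domain, %g um^2\n", object@domainType,
              object@domainArea))
  show(object@sim)
  if (!is.null(object@stimulus)) show(object@stimulus)
})

#' Build the domain described by a run configuration
#' @param config a \code{RunConfig}
#' @return a \code{Domain}
#' @export
buildDomain <- function(config) {
  if (config@domainType == "ring")
    ringFromFrontArea(config@domainArea, config@nNodes)
  else sphereFromFrontArea(config@domainArea, config@level)
}

.configKeys <- function() {
  numKey <- function(block, name, get, set, positive = TRUE)
    list(block = block, name = name, get = get, set = set,
         positive = positive)
  keys <- list()
  for (nm in gmParameterNames()) {
    local({
      p <- nm
      keys[[paste0("model.", p)]] <<-
        numKey("model", p, function(cfg) slot(cfg@params, p),
               function(cfg, v) { slot(cfg@params, p) <- v; cfg })
    })
  }
  keys[["domain.type"]] <- list(block = "domain", name = "type",
    get = function(cfg) cfg@domainType,
    set = function(cfg, v) { cfg@domainType <- v; cfg }, positive = NA)
  keys[["domain.front_area"]] <- numKey("domain", "front_area",
    function(cfg) cfg@domainArea,
    function(cfg, v) { cfg@domainArea <- v; cfg })
  keys[["domain.n_nodes"]] <- numKey("domain", "n_nodes",
    function(cfg) cfg@nNodes,
    function(cfg, v) { cfg@nNodes <- as.integer(v); cfg })
  keys[["domain.level"]] <- numKey("domain", "level",
    function(cfg) cfg@level,
    function(cfg, v) { cfg@level <- as.integer(v); cfg })
  keys[["sim.noise_amp"]] <- numKey("sim", "noise_amp",
    function(cfg) cfg@sim@noiseAmp,
    function(cfg, v) { cfg@sim@noiseAmp <- v; cfg }, positive = FALSE)
  keys[["sim.seed"]] <- numKey("sim", "seed",
    function(cfg) cfg@sim@seed,
    function(cfg, v) { cfg@sim@seed <- as.integer(v); cfg },
    positive = FALSE)
  keys[["sim.t_max"]] <- numKey("sim", "t_max",
    function(cfg) cfg@sim@tMax,
    function(cfg, v) { cfg@sim@tMax <- v; cfg })
  keys[["sim.steady_tol"]] <- numKey("sim", "steady_tol",
    function(cfg) cfg@sim@steadyTol,
    function(cfg, v) { cfg@sim@steadyTol <- v; cfg })
  keys[["sim.dt"]] <- numKey("sim", "dt",
    function(cfg) cfg@sim@dt,
    function(cfg, v) { cfg@sim@dt <- v; cfg })
  keys[["stimulus.mode"]] <- list(block = "stimulus", name = "mode",
    get = function(cfg) if (is.null(cfg@stimulus)) NULL
                        else cfg@stimulus@mode,
    set = function(cfg, v) { cfg <- .ensureStim(cfg)
      cfg@stimulus@mode <- v; cfg }, positive = NA)
  keys[["stimulus.pattern"]] <- list(block = "stimulus", name = "pattern",
    get = function(cfg) if (is.null(cfg@stimulus)) NULL
                        else cfg@stimulus@pattern,
    set = function(cfg, v) { cfg <- .ensureStim(cfg)
      cfg@stimulus@pattern <- v; cfg }, positive = NA)
  keys[["stimulus.amplitude"]] <- numKey("stimulus", "amplitude",
    function(cfg) if (is.null(cfg@stimulus)) NULL
                  else cfg@stimulus@amplitude,
    function(cfg, v) { cfg <- .ensureStim(cfg)
      cfg@stimulus@amplitude <- v; cfg })
  keys[["stimulus.k"]] <- numKey("stimulus", "k",
    function(cfg) if (is.null(cfg@stimulus)) NULL else cfg@stimulus@k,
    function(cfg, v) { cfg <- .ensureStim(cfg)
      cfg@stimulus@k <- as.integer(v); cfg })
  keys
}

.ensureStim <- function(cfg) {
  if (is.null(cfg@stimulus))
    cfg@stimulus <- stimulusSpec("transient", "equatorial", 1e-3, 3L)
  cfg
}

#' Read a run configuration from a plain-text file
#'
#' Parses a flat \code{key = value} file (one entry per line, \code{#}
#' comments) with dotted keys \code{model.*}, \code{domain.*},
#' \code{sim.*}, \code{stimulus.*} -- see \code{\link{saveRunConfig}} for
#' the full schema.  Omitted keys keep their wild-type defaults; unknown
#' keys and invalid values are rejected with an error naming the key.
#'
#' @param path file path; an empty file yields the full default
#'   configuration
#' @return a validated \code{RunConfig}
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- runConfig()
  keys <- .configKeys()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("malformed config line (expected key = value): '%s'",
                   ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    spec <- keys[[key]]
    if (is.null(spec)) stop(sprintf("unknown config key '%s'", key))
    if (isTRUE(is.na(spec$positive))) {      # string-valued key
      cfg <- spec$set(cfg, val)
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop(sprintf("config key '%s' must be numeric, got '%s'", key,
                     val))
      if (isTRUE(spec$positive) && num <= 0)
        stop(sprintf("config key '%s' must be positive, got %g", key,
                     num))
      cfg <- spec$set(cfg, num)
    }
  }
  validObject(cfg@params)
  validObject(cfg@sim)
  if (!cfg@domainType %in% c("ring", "sphere"))
    stop("config key 'domain.type' must be 'ring' or 'sphere'")
  if (!is.null(cfg@stimulus)) validObject(cfg@stimulus)
  cfg
}

#' Write a run configuration as a plain-text file
#'
#' Writes the normalized flat \code{key = value} form read back by
#' \code{\link{readRunConfig}} (round trip: \code{save(load(x))} equals
#' \code{normalize(x)}).
#'
#' @param config a \code{RunConfig}
#' @param path output file path
#' @return invisibly, the path
#' @export
saveRunConfig <- function(config, path) {
  keys <- .configKeys()
  lines <- c("# PollenGM run configuration")
  for (key in names(keys)) {
    v <- keys[[key]]$get(config)
    if (is.null(v)) next
    lines <- c(lines, sprintf("%s = %s", key,
                              if (is.numeric(v)) format(v, digits = 15)
                              else v))
  }
  writeLines(lines, path)
  invisible(path)
}

.paramsSignature <- function(pl)
  paste(vapply(pl, function(v) format(v, digits = 15), character(1)),
        collapse = "|")

#' Save / load a morphogen field
#'
#' A field is stored as two plain-text files: \code{<path>} holds the
#' per-node table (node coordinates, A, H) as CSV and \code{<path>.json} a
#' manifest with the domain descriptor, time, reference steady state,
#' seed and a parameter signature.  \code{loadField} rebuilds the domain
#' from the descriptor and errors on any shape mismatch; node values round
#' trip bit-exactly.
#'
#' @param field a \code{Field}
#' @param path CSV file path (manifest written alongside)
#' @return \code{saveField}: invisibly, the path; \code{loadField}: the
#'   reconstructed \code{Field}
#' @export
saveField <- function(field, path) {
  domain <- field@domain
  if (is(domain, "RingDomain")) {
    tab <- data.frame(s = domain@positions, A = field@A, H = field@H)
    desc <- list(type = "ring", front_area = domain@frontArea,
                 n_nodes = domain@nNodes)
  } else {
    tab <- data.frame(x = domain@vertices[, 1], y = domain@vertices[, 2],
                      z = domain@vertices[, 3], A = field@A, H = field@H)
    desc <- list(type = "sphere", front_area = domain@frontArea,
                 level = domain@level)
  }
  utils::write.csv(format(tab, digits = 17), path, row.names = FALSE,
                   quote = FALSE)
  manifest <- list(domain = desc, time = field@time,
                   ref = as.list(field@ref), meta = field@meta)
  if (!is.null(field@meta$params))
    manifest$params_signature <- .paramsSignature(field@meta$params)
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname saveField
#' @export
loadField <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".json"),
                                  simplifyVector = TRUE)
  tab <- utils::read.csv(path)
  desc <- manifest$domain
  domain <- if (identical(desc$type, "ring"))
    ringFromFrontArea(desc$front_area, desc$n_nodes)
  else sphereFromFrontArea(desc$front_area, desc$level)
  if (nrow(tab) != nNodes(domain))
    stop(sprintf(paste0("field shape mismatch: file has %d nodes but the",
                        " %s domain descriptor yields %d"),
                 nrow(tab), desc$type, nNodes(domain)))
  meta <- manifest$meta
  if (is.null(meta)) meta <- list()
  new("Field", domain = domain, A = tab$A, H = tab$H,
      time = if (is.null(manifest$time)) NA_real_ else manifest$time,
      ref = c(A = manifest$ref$A, H = manifest$ref$H),
      meta = as.list(meta))
}

#' Write a Turing report as JSON
#' @param report a \code{TuringReport}
#' @param path output file path
#' @return invisibly, the path
#' @export
writeTuringReport <- function(report, path) {
  lin <- report@linearization
  jsonlite::write_json(list(
    stable_without_diffusion = report@stableWithoutDiffusion,
    diffusion_driven_instability = report@diffusionDrivenInstability,
    satisfied = report@satisfied,
    k2_minus = report@k2Minus, k2_plus = report@k2Plus,
    steady_state = list(A = report@steadyState@A,
                        H = report@steadyState@H),
    linearization = list(f_A = lin@f_A, f_H = lin@f_H, g_A = lin@g_A,
                         g_H = lin@g_H, trace = lin@trace,
                         det = lin@det)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
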