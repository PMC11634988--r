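#' @import methods
NULL

#' PCR assay description
#'
#' An S4 container for the physical constants of one PCR assay: the reaction
#' volume, the qPCR cycle cap after which a reaction is reported as
#' non-detect, and the ddPCR droplet (partition) volume.
#'
#' @slot assayId single character label, e.g. `"cod"`.
#' @slot reactionVolumeUl reaction volume in microlitres (default 20).
#' @slot maxCycles maximum qPCR cycle number; a reaction whose fluorescence
#'   never crosses threshold within `maxCycles` is a non-detect.
#' @slot dropletVolumeUl ddPCR droplet volume in microlitres
#'   (default 0.00085, the manufacturer value for the QX200 system).
#' @export
setClass("PcrAssay",
  representation(
    assayId = "character",
    reactionVolumeUl = "numeric",
    maxCycles = "integer",
    dropletVolumeUl = "numeric"
  )
)

setValidity("PcrAssay", function(object) {
  msg <- character()
  if (length(object@assayId) != 1L || !nzchar(object@assayId))
    msg <- c(msg, "assayId must be a single non-empty string")
  if (length(object@reactionVolumeUl) != 1L ||
      !is.finite(object@reactionVolumeUl) || object@reactionVolumeUl <= 0)
    msg <- c(msg, "reactionVolumeUl must be a single positive number")
  if (length(object@maxCycles) != 1L || is.na(object@maxCycles) ||
      object@maxCycles < 1L)
    msg <- c(msg, "maxCycles must be a positive integer")
  if (length(object@dropletVolumeUl) != 1L ||
      !is.finite(object@dropletVolumeUl) || object@dropletVolumeUl <= 0)
    msg <- c(msg, "dropletVolumeUl must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a PcrAssay
#'
#' @param assayId short assay label.
#' @param reactionVolumeUl reaction volume, microlitres.
#' @param maxCycles qPCR cycle cap (42, 45 or 52 are common instrument
#'   settings).
#' @param dropletVolumeUl ddPCR droplet volume, microlitres.
#' @return A [PcrAssay-class] object.
#' @examples
#' cod <- PcrAssay("cod", maxCycles = 45)
#' assayId(cod)
#' @export
PcrAssay <- function(assayId, reactionVolumeUl = 20, maxCycles = 45L,
                     dropletVolumeUl = 0.00085) {
  new("PcrAssay", assayId = as.character(assayId),
      reactionVolumeUl = as.numeric(reactionVolumeUl),
      maxCycles = as.integer(maxCycles),
      dropletVolumeUl = as.numeric(dropletVolumeUl))
}

#' qPCR calibration parameters
#'
#' Parameters of the two-step qPCR calibration model. The detection
#' component is logistic in log10 concentration with intercept `phi0` and
#' slope `phi1`; conditional on detection, the cycle threshold (Ct) is
#' Normal with mean `beta0 + beta1 * log10(C)` and standard deviation
#' `exp(gamma0 + gamma1 * log10(C))`.
#'
#' Validity requires `phi1 > 0` (detection probability non-decreasing in
#' concentration) and `beta1 < 0` (Ct decreases as template increases;
#' `beta1 = -3.32` corresponds to 100% amplification efficiency).
#'
#' @slot phi0,phi1 logistic detection intercept and slope.
#' @slot beta0,beta1 Ct mean intercept and slope.
#' @slot gamma0,gamma1 log-scale Ct standard deviation intercept and slope.
#' @export
setClass("QpcrParams",
  representation(phi0 = "numeric", phi1 = "numeric",
                 beta0 = "numeric", beta1 = "numeric",
                 gamma0 = "numeric", gamma1 = "numeric")
)

setValidity("QpcrParams", function(object) {
  vals <- c(object@phi0, object@phi1, object@beta0, object@beta1,
            object@gamma0, object@gamma1)
  if (length(vals) != 6L || !all(is.finite(vals)))
    return("all six parameters must be single finite numbers")
  msg <- character()
  if (object@phi1 <= 0) msg <- c(msg, "phi1 must be > 0")
  if (object@beta1 >= 0) msg <- c(msg, "beta1 must be < 0")
  if (length(msg)) msg else TRUE
})

#' Construct qPCR calibration parameters
#'
#' @param phi0,phi1 detection-logistic intercept and slope (`phi1 > 0`).
#' @param beta0,beta1 Ct-mean intercept and slope (`beta1 < 0`).
#' @param gamma0,gamma1 intercept and slope of the log Ct standard
#'   deviation.
#' @return A [QpcrParams-class] object.
#' @examples
#' QpcrParams(phi0 = 1.5, phi1 = 2.2, beta0 = 38, beta1 = -3.32,
#'            gamma0 = -1.2, gamma1 = -0.25)
#' @export
QpcrParams <- function(phi0, phi1, beta0, beta1, gamma0, gamma1) {
  new("QpcrParams", phi0 = as.numeric(phi0), phi1 = as.numeric(phi1),
      beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
      gamma0 = as.numeric(gamma0), gamma1 = as.numeric(gamma1))
}

#' ddPCR calibration parameters
#'
#' Intercept and slope of the complementary log-log line relating the
#' positive-droplet probability to log10 concentration:
#' `cloglog(omega) = kappa0 + kappa1 * log10(C)`. For an assay with 100%
#' efficiency, `kappa0 = log(V)` (V the droplet volume in microlitres) and
#' `kappa1 = log(10)`.
#'
#' @slot kappa0 cloglog intercept (log droplet volume at 100% efficiency).
#' @slot kappa1 cloglog slope (`log(10)` at 100% efficiency; must be > 0).
#' @export
setClass("DdpcrParams",
  representation(kappa0 = "numeric", kappa1 = "numeric")
)

setValidity("DdpcrParams", function(object) {
  vals <- c(object@kappa0, object@kappa1)
  if (length(vals) != 2L || !all(is.finite(vals)))
    return("kappa0 and kappa1 must be single finite numbers")
  if (object@kappa1 <= 0) return("kappa1 must be > 0")
  TRUE
})

#' Construct ddPCR calibration parameters
#'
#' @param kappa0 cloglog intercept.
#' @param kappa1 cloglog slope, must be positive.
#' @return A [DdpcrParams-class] object.
#' @examples
#' DdpcrParams(kappa0 = log(0.00085), kappa1 = log(10))
#' @export
DdpcrParams <- function(kappa0, kappa1) {
  new("DdpcrParams", kappa0 = as.numeric(kappa0), kappa1 = as.numeric(kappa1))
}

#' Simulation design for synthetic plate data
#'
#' Describes one synthetic plate: the standard dilution series, replicate
#' counts, the environmental ("unknown") samples, true-absence samples, and
#' the droplet-count distribution for ddPCR.
#'
#' Unknown-sample true concentrations are either given explicitly
#' (`unknownLog10Concs`) or drawn at simulation time from
#' `Normal(unknownLog10Mean, unknownLog10Sd)` — the low-concentration regime
#' typical of eDNA (roughly 1e-2 to 1 copies/uL).
#'
#' @slot platform `"qpcr"` or `"ddpcr"`.
#' @slot standardConcs nominal standard concentrations, copies/uL.
#' @slot nStandardReps technical replicates per standard.
#' @slot unknownLog10Concs explicit true log10 concentrations for unknowns
#'   (may be empty, in which case `nUnknown` values are drawn).
#' @slot nUnknown number of unknown samples when drawing truths.
#' @slot unknownLog10Mean,unknownLog10Sd sampling distribution of unknown
#'   true log10 concentrations.
#' @slot nUnknownReps technical replicates per unknown.
#' @slot nAbsentSamples number of true-absence samples (concentration 0).
#' @slot nNegativeControls number of no-template control wells.
#' @slot dropletsMean mean droplets per ddPCR reaction (default 20000).
#' @slot dropletsDispersion droplet-count coefficient of variation.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationDesign",
  representation(
    platform = "character",
    standardConcs = "numeric",
    nStandardReps = "integer",
    unknownLog10Concs = "numeric",
    nUnknown = "integer",
    unknownLog10Mean = "numeric",
    unknownLog10Sd = "numeric",
    nUnknownReps = "integer",
    nAbsentSamples = "integer",
    nNegativeControls = "integer",
    dropletsMean = "integer",
    dropletsDispersion = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (!object@platform %in% c("qpcr", "ddpcr"))
    msg <- c(msg, "platform must be 'qpcr' or 'ddpcr'")
  if (length(object@standardConcs) < 1L ||
      any(!is.finite(object@standardConcs) | object@standardConcs <= 0))
    msg <- c(msg, "standardConcs must all be positive")
  if (object@nStandardReps < 1L || object@nUnknownReps < 1L)
    msg <- c(msg, "replicate counts must be >= 1")
  if (object@nAbsentSamples < 0L || object@nNegativeControls < 0L)
    msg <- c(msg, "sample counts must be non-negative")
  if (object@dropletsMean < 1L)
    msg <- c(msg, "dropletsMean must be positive")
  if (object@dropletsDispersion < 0)
    msg <- c(msg, "dropletsDispersion must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Posterior fit of a PCR calibration model
#'
#' Result container returned by [fitQpcr()], [fitDdpcr()] and
#' [fitDetectionLogistic()]: posterior draws, MCMC diagnostics, and (for the
#' quantification fitters) per-sample concentration estimates.
#'
#' @slot platform `"qpcr"`, `"ddpcr"` or `"detection"`.
#' @slot mode model variant, e.g. `"two_step"` or `"continuous_only"`.
#' @slot draws a [coda::mcmc.list] of posterior draws, one element per
#'   chain; latent unknown concentrations appear as `log10C[<sample_id>]`.
#' @slot nChains,nIter number of chains and post-warmup iterations/chain.
#' @slot rhat,ess named per-parameter potential scale reduction factors and
#'   effective sample sizes (summed over chains).
#' @slot converged TRUE only when `max(rhat) < 1.05` and `min(ess) >= 400`.
#' @slot seed the seed the sampler was run with.
#' @slot estimates data.frame of per-sample [concentration
#'   estimates][estimates] (empty for detection-only fits).
#' @slot notes character vector of fitter warnings (e.g. saturated wells
#'   dropped, prior-driven samples).
#' @export
setClass("PcrFit",
  representation(
    platform = "character",
    mode = "character",
    draws = "ANY",
    nChains = "integer",
    nIter = "integer",
    rhat = "numeric",
    ess = "numeric",
    converged = "logical",
    seed = "integer",
    estimates = "data.frame",
    notes = "character"
  )
)
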