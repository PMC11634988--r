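# Synthetic plate generator: draws qPCR and ddPCR plates from exactly the
# generative structure the calibration models assume, so that parameter
# recovery and precision comparisons can be run without field data.

#' Default simulation design
#'
#' Returns the study-style design for one synthetic plate: a 10-fold
#' standard dilution series (1e-1 to 1e6 copies/uL for qPCR; 1e-3 to 1e4
#' for ddPCR), technical triplicates, 30 environmental unknowns with true
#' log10 concentration drawn from Normal(-1, 1.5), 5 true-absence samples
#' and 2 no-template controls. ddPCR reactions target 20,000 droplets with
#' a 5% coefficient of variation.
#'
#' @param platform `"qpcr"` or `"ddpcr"`.
#' @param seed integer seed stored in the design.
#' @return a [SimulationDesign-class].
#' @examples
#' defaultDesign("ddpcr")@standardConcs
#' @export
defaultDesign <- function(platform = c("qpcr", "ddpcr"), seed = 1L) {
  platform <- match.arg(platform)
  concs <- if (platform == "qpcr") 10^(-1:6) else 10^(-3:4)
  new("SimulationDesign",
      platform = platform,
      standardConcs = concs,
      nStandardReps = 3L,
      unknownLog10Concs = numeric(0),
      nUnknown = 30L,
      unknownLog10Mean = -1,
      unknownLog10Sd = 1.5,
      nUnknownReps = 3L,
      nAbsentSamples = 5L,
      nNegativeControls = 2L,
      dropletsMean = 20000L,
      dropletsDispersion = 0.05,
      seed = as.integer(seed))
}

#' Modify a simulation design
#'
#' Convenience copy-constructor: returns `design` with the named slots
#' replaced.
#'
#' @param design a [SimulationDesign-class].
#' @param ... slot = value pairs, e.g. `nUnknown = 20L`, `seed = 7L`.
#' @return the modified design (validity re-checked).
#' @export
updateDesign <- function(design, ...) {
  args <- list(...)
  for (nm in names(args)) {
    proto <- slot(design, nm)
    slot(design, nm) <- if (is.integer(proto)) as.integer(args[[nm]])
                        else as(args[[nm]], class(proto))
  }
  validObject(design)
  design
}

# Runs expr under a private RNG stream, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Builds the per-sample frame (id, type, nominal conc, true log10 C, reps)
# shared by both platforms. Absent samples have trueLog10 = -Inf.
.designSamples <- function(design) {
  nStd <- length(design@standardConcs)
  std <- data.frame(
    sample_id = sprintf("STD%02d", seq_len(nStd)),
    sample_type = "standard",
    nominal_conc = design@standardConcs,
    true_log10 = log10(design@standardConcs),
    n_reps = design@nStandardReps)
  if (length(design@unknownLog10Concs)) {
    trueU <- design@unknownLog10Concs
  } else {
    trueU <- stats::rnorm(design@nUnknown, design@unknownLog10Mean,
                          design@unknownLog10Sd)
  }
  block <- function(ids, type, true, reps) {
    n <- length(ids)
    data.frame(sample_id = ids, sample_type = rep(type, n),
               nominal_conc = rep(NA_real_, n),
               true_log10 = rep_len(true, n), n_reps = rep(reps, n))
  }
  rbind(std,
        block(sprintf("UNK%02d", seq_along(trueU)), "unknown", trueU,
              design@nUnknownReps),
        block(sprintf("ABS%02d", seq_len(design@nAbsentSamples)), "unknown",
              -Inf, design@nUnknownReps),
        block(sprintf("NTC%02d", seq_len(design@nNegativeControls)),
              "negative_control", -Inf, 1L))
}

.checkParamsFinite <- function(params) {
  vals <- vapply(slotNames(params), function(s) slot(params, s), numeric(1))
  if (!all(is.finite(vals)))
    stop("simulation parameters must all be finite")
}

#' Simulate a qPCR plate
#'
#' Draws reaction records from the two-step generative model: for a
#' reaction at true log10 concentration c, detection is
#' `Z ~ Bernoulli(plogis(phi0 + phi1 * c))`; conditional on detection the
#' cycle threshold is `Ct ~ Normal(beta0 + beta1 * c,
#' exp(gamma0 + gamma1 * c))`. A detected draw that lands beyond the
#' assay's `maxCycles` is censored by the instrument and recorded as
#' non-detect (mirroring a plate whose run ends before the curve crosses
#' threshold). True-absence samples and negative controls never amplify.
#'
#' @param params a [QpcrParams-class] of true generator values.
#' @param design a [SimulationDesign-class] (`platform` must be "qpcr").
#' @param assay a [PcrAssay-class]; supplies `maxCycles`.
#' @param seed optional integer overriding `design@seed`.
#' @return data.frame of reaction records (same schema as
#'   [readQpcrTable()]), with the per-sample truth table attached as
#'   `attr(x, "truth")` (columns `sample_id`, `true_log10`).
#' @examples
#' p <- QpcrParams(1.5, 2.2, 38, -3.32, -1.2, -0.25)
#' plate <- simulateQpcr(p, defaultDesign("qpcr"), PcrAssay("cod"))
#' head(plate)
#' @export
simulateQpcr <- function(params, design, assay, seed = NULL) {
  stopifnot(is(params, "QpcrParams"), is(design, "SimulationDesign"),
            is(assay, "PcrAssay"))
  if (design@platform != "qpcr")
    stop("design platform is '", design@platform, "', expected 'qpcr'")
  .checkParamsFinite(params)
  seed <- if (is.null(seed)) design@seed else as.integer(seed)
  .withSeed(seed, {
    samples <- .designSamples(design)
    rows <- samples[rep(seq_len(nrow(samples)), samples$n_reps), ]
    rows$replicate <- sequence(samples$n_reps)
    n <- nrow(rows)
    theta <- ifelse(is.finite(rows$true_log10),
                    stats::plogis(params@phi0 + params@phi1 * rows$true_log10),
                    0)
    z <- stats::rbinom(n, 1L, theta) == 1L
    mu <- params@beta0 + params@beta1 * rows$true_log10
    sdv <- exp(params@gamma0 + params@gamma1 * rows$true_log10)
    ct <- rep(NA_real_, n)
    ct[z] <- stats::rnorm(sum(z), mu[z], sdv[z])
    censored <- z & (ct > assay@maxCycles | ct <= 0)
    ct[censored | !z] <- NA_real_
    out <- data.frame(
      assay_id = assay@assayId,
      sample_id = rows$sample_id,
      sample_type = rows$sample_type,
      nominal_conc = rows$nominal_conc,
      replicate = rows$replicate,
      ct = ct,
      detected = !is.na(ct),
      row.names = NULL)
    attr(out, "truth") <- data.frame(sample_id = samples$sample_id,
                                     true_log10 = samples$true_log10,
                                     row.names = NULL)
    out
  })
}

#' Simulate a ddPCR plate
#'
#' Draws droplet records from the binomial/cloglog generative model: the
#' total droplet count is `U ~ round(Normal(dropletsMean,
#' dropletsDispersion * dropletsMean))`, floored at 1,000; the
#' positive-droplet probability at true log10 concentration c is
#' `omega = 1 - exp(-exp(kappa0 + kappa1 * c))` and
#' `W ~ Binomial(U, omega)`. True-absence samples and negative controls
#' have `omega = 0`, hence `W = 0`.
#'
#' @param params a [DdpcrParams-class] of true generator values.
#' @param design a [SimulationDesign-class] (`platform` must be "ddpcr").
#' @param assay a [PcrAssay-class].
#' @param seed optional integer overriding `design@seed`.
#' @return data.frame of droplet records (same schema as
#'   [readDdpcrTable()]) with truth attached as `attr(x, "truth")`.
#' @examples
#' k <- DdpcrParams(log(0.00085), log(10))
#' plate <- simulateDdpcr(k, defaultDesign("ddpcr"), PcrAssay("cod"))
#' head(plate)
#' @export
simulateDdpcr <- function(params, design, assay, seed = NULL) {
  stopifnot(is(params, "DdpcrParams"), is(design, "SimulationDesign"),
            is(assay, "PcrAssay"))
  if (design@platform != "ddpcr")
    stop("design platform is '", design@platform, "', expected 'ddpcr'")
  .checkParamsFinite(params)
  seed <- if (is.null(seed)) design@seed else as.integer(seed)
  .withSeed(seed, {
    samples <- .designSamples(design)
    rows <- samples[rep(seq_len(nrow(samples)), samples$n_reps), ]
    rows$replicate <- sequence(samples$n_reps)
    n <- nrow(rows)
    u <- pmax(1000L, as.integer(round(stats::rnorm(
      n, design@dropletsMean,
      design@dropletsDispersion * design@dropletsMean))))
    omega <- ifelse(is.finite(rows$true_log10),
                    -expm1(-exp(params@kappa0 + params@kappa1 *
                                  rows$true_log10)),
                    0)
    w <- stats::rbinom(n, u, omega)
    out <- data.frame(
      assay_id = assay@assayId,
      sample_id = rows$sample_id,
      sample_type = rows$sample_type,
      nominal_conc = rows$nominal_conc,
      replicate = rows$replicate,
      positive_droplets = w,
      total_droplets = u,
      row.names = NULL)
    attr(out, "truth") <- data.frame(sample_id = samples$sample_id,
                                     true_log10 = samples$true_log10,
                                     row.names = NULL)
    out
  })
}

#' Default generator truths
#'
#' Reference parameter values used throughout the examples and tests:
#' qPCR `phi0 = 1.5, phi1 = 2.2, beta0 = 38, beta1 = -3.32` (the slope of a
#' 100%-efficient standard curve), `gamma0 = -1.2, gamma1 = -0.25` (Ct
#' scatter grows as concentration falls); ddPCR `kappa0 = log(0.00085)`
#' (the manufacturer droplet volume) and `kappa1 = log(10)` (100%
#' efficiency).
#'
#' @return a [QpcrParams-class] or [DdpcrParams-class].
#' @export
defaultQpcrParams <- function() {
  QpcrParams(phi0 = 1.5, phi1 = 2.2, beta0 = 38, beta1 = -3.32,
             gamma0 = -1.2, gamma1 = -0.25)
}

#' @rdname defaultQpcrParams
#' @export
defaultDdpcrParams <- function() {
  DdpcrParams(kappa0 = log(0.00085), kappa1 = log(10))
}
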