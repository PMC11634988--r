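# Two-step (hurdle) qPCR calibration model: a Bernoulli detection
# component on all reactions plus a Normal Ct component on detected ones,
# fitted jointly over standards and unknowns so the dilution series informs
# the latent concentration of every environmental sample.

#' Detection probability of the qPCR model
#'
#' `plogis(phi0 + phi1 * log10_c)` — the probability that a single reaction
#' at log10 concentration `log10_c` amplifies.
#'
#' @param params a [QpcrParams-class].
#' @param log10_c log10 concentration(s), copies/uL (vectorised).
#' @return detection probabilities in (0, 1).
#' @examples
#' qpcrDetectionProb(defaultQpcrParams(), log10_c = -1:3)
#' @export
qpcrDetectionProb <- function(params, log10_c) {
  stopifnot(is(params, "QpcrParams"))
  stats::plogis(params@phi0 + params@phi1 * log10_c)
}

#' Conditional Ct mean and standard deviation
#'
#' The cycle threshold of a detected reaction is Normal with mean
#' `beta0 + beta1 * log10_c` and standard deviation
#' `exp(gamma0 + gamma1 * log10_c)` (log-linear, so Ct scatter can grow as
#' template becomes scarce).
#'
#' @inheritParams qpcrDetectionProb
#' @return data.frame with columns `mean_ct` and `sd_ct` (one row per
#'   element of `log10_c`).
#' @examples
#' qpcrCtMoments(defaultQpcrParams(), log10_c = 3)
#' @export
qpcrCtMoments <- function(params, log10_c) {
  stopifnot(is(params, "QpcrParams"))
  data.frame(mean_ct = params@beta0 + params@beta1 * log10_c,
             sd_ct = exp(params@gamma0 + params@gamma1 * log10_c))
}

# Per-record log10 concentration: standards use their nominal value,
# unknowns look up the supplied latent map.
.recordLog10C <- function(records, log10_c_by_sample) {
  c_vec <- rep(NA_real_, nrow(records))
  std <- records$sample_type == "standard"
  c_vec[std] <- log10(records$nominal_conc[std])
  unk <- !std
  if (any(unk)) {
    hit <- match(records$sample_id[unk], names(log10_c_by_sample))
    if (anyNA(hit))
      stop("no latent log10 concentration supplied for sample(s): ",
           paste(unique(records$sample_id[unk][is.na(hit)]), collapse = ", "))
    c_vec[unk] <- log10_c_by_sample[hit]
  }
  c_vec
}

#' Joint log-likelihood of the two-step qPCR model
#'
#' Sums, over all reactions, the Bernoulli detection log-probability
#' `Z * log(theta) + (1 - Z) * log(1 - theta)` and, over detected
#' reactions, the Normal log-density of the observed Ct at the
#' concentration-dependent mean and standard deviation. Standards
#' contribute at their nominal log10 concentration; unknowns at the latent
#' value supplied in `log10_c_by_sample`. Negative-control records are
#' excluded.
#'
#' @param params a [QpcrParams-class].
#' @param log10_c_by_sample named numeric vector: latent log10
#'   concentration per unknown `sample_id`.
#' @param records reaction records (see [readQpcrTable()]).
#' @return the scalar log-likelihood.
#' @export
qpcrLogLikelihood <- function(params, log10_c_by_sample, records) {
  stopifnot(is(params, "QpcrParams"))
  records <- records[records$sample_type != "negative_control", , drop = FALSE]
  det <- if ("detected" %in% names(records)) records$detected
         else !is.na(records$ct)
  c_vec <- .recordLog10C(records, log10_c_by_sample)
  theta <- stats::plogis(params@phi0 + params@phi1 * c_vec)
  ll <- sum(ifelse(det, log(theta), log1p(-theta)))
  if (any(det)) {
    mu <- params@beta0 + params@beta1 * c_vec[det]
    sdv <- exp(params@gamma0 + params@gamma1 * c_vec[det])
    ll <- ll + sum(stats::dnorm(records$ct[det], mu, sdv, log = TRUE))
  }
  ll
}

#' Priors for the qPCR calibration model
#'
#' Weakly informative defaults centred on PCR physics: the Ct slope prior
#' sits on -3.32 (a 100%-efficient curve) and the latent log10
#' concentration prior is wide enough to cover 1e-3 to 1e6 copies/uL.
#' `phi1` is truncated positive and `beta1` negative, matching the
#' [QpcrParams-class] invariants.
#'
#' @param phi0,phi1,beta0,beta1,gamma0,gamma1,log10C each a
#'   `list(mu =, sd =)` Normal prior specification.
#' @return a named list of prior specifications.
#' @export
qpcrPriors <- function(phi0 = list(mu = 0, sd = 5),
                       phi1 = list(mu = 1, sd = 2),
                       beta0 = list(mu = 40, sd = 10),
                       beta1 = list(mu = -3.32, sd = 2),
                       gamma0 = list(mu = 0, sd = 2),
                       gamma1 = list(mu = 0, sd = 1),
                       log10C = list(mu = 0, sd = 3)) {
  pr <- list(phi0 = phi0, phi1 = phi1, beta0 = beta0, beta1 = beta1,
             gamma0 = gamma0, gamma1 = gamma1, log10C = log10C)
  ok <- vapply(pr, function(p) is.numeric(p$mu) && is.numeric(p$sd) &&
                 is.finite(p$mu) && is.finite(p$sd) && p$sd > 0, TRUE)
  if (!all(ok))
    stop("invalid prior specification for: ",
         paste(names(pr)[!ok], collapse = ", "))
  pr
}

# Intercept/slope pairs are sampled in a centered parameterisation
# (intercept shifted to the mean standard log10 concentration, passed as
# data `cbar`) to decorrelate the Gibbs updates; the conditional prior on
# the centered intercept is chosen so the independent Normal priors on the
# original (phi0, beta0, gamma0) are preserved exactly.
.centeredPairText <- function(stem, priorInt, priorSlope, lower = NULL,
                              upper = NULL, cbarName = "cbar") {
  paste0(
    .dnormText(paste0(stem, "1"), priorSlope, lower = lower, upper = upper),
    sprintf("  %sC ~ dnorm(%.17g + %s1 * %s, %.17g)\n",
            stem, priorInt$mu, stem, cbarName, 1 / priorInt$sd^2),
    sprintf("  %s0 <- %sC - %s1 * %s\n", stem, stem, stem, cbarName))
}

.qpcrModelString <- function(priors, mode, fixed, counts) {
  lines <- "model {\n"
  if (!fixed) {
    if (mode == "two_step")
      lines <- c(lines,
        .centeredPairText("phi", priors$phi0, priors$phi1, lower = 0,
                          cbarName = "cbarPhi"))
    lines <- c(lines,
      .centeredPairText("beta", priors$beta0, priors$beta1, upper = 0),
      .centeredPairText("gamma", priors$gamma0, priors$gamma1))
  }
  if (counts$nu > 0L)
    lines <- c(lines, sprintf(
      "  for (j in 1:%d) { lc[j] ~ dnorm(%.17g, %.17g) }\n",
      counts$nu, priors$log10C$mu, 1 / priors$log10C$sd^2))
  if (mode == "two_step") {
    if (counts$ns > 0L)
      lines <- c(lines, sprintf(
        "  for (r in 1:%d) { zs[r] ~ dbern(ilogit(phi0 + phi1 * cs[r])) }\n",
        counts$ns))
    if (counts$nuw > 0L)
      lines <- c(lines, sprintf(
        "  for (r in 1:%d) { zu[r] ~ dbern(ilogit(phi0 + phi1 * lc[iu[r]])) }\n",
        counts$nuw))
  }
  if (counts$nsd > 0L)
    lines <- c(lines, sprintf(paste0(
      "  for (r in 1:%d) { ysd[r] ~ dnorm(beta0 + beta1 * csd[r],",
      " pow(exp(gamma0 + gamma1 * csd[r]), -2)) }\n"), counts$nsd))
  if (counts$nud > 0L)
    lines <- c(lines, sprintf(paste0(
      "  for (r in 1:%d) { yud[r] ~ dnorm(beta0 + beta1 * lc[iud[r]],",
      " pow(exp(gamma0 + gamma1 * lc[iud[r]]), -2)) }\n"), counts$nud))
  paste0(c(lines, "}\n"), collapse = "")
}

#' Fit the Bayesian qPCR quantification model
#'
#' Jointly estimates the calibration parameters and the latent log10
#' concentration of every unknown sample from one assay's plate records.
#' In `"two_step"` mode the detection (Bernoulli/logistic) and continuous
#' (Normal Ct) components are combined, so non-detected replicates carry
#' information; `"continuous_only"` drops the detection component (the
#' ablation used to measure the precision the detection step adds), and an
#' unknown whose replicates are all non-detect is then prior-driven and
#' flagged as such in the estimate table.
#'
#' @param records reaction records for a single assay (from
#'   [readQpcrTable()] or [simulateQpcr()]). Negative controls are excluded
#'   from the fit unless `includeControls = TRUE`, which treats them as
#'   unknowns.
#' @param priors from [qpcrPriors()].
#' @param config from [mcmcConfig()].
#' @param mode `"two_step"` or `"continuous_only"`.
#' @param fixedParams optional [QpcrParams-class]; when given, calibration
#'   parameters are held at these values and only the latent
#'   concentrations are sampled (used for oracle checks).
#' @param detectThreshold concentration (copies/uL) below which a posterior
#'   median is classified non-detect; default 1e-3.
#' @param includeControls treat negative-control wells as unknown samples.
#' @return a [PcrFit-class]; latent draws are named
#'   `log10C[<sample_id>]`, and [estimates()] returns the per-sample
#'   summary table.
#' @examples
#' \donttest{
#' plate <- simulateQpcr(defaultQpcrParams(),
#'                       updateDesign(defaultDesign("qpcr"), nUnknown = 5L),
#'                       PcrAssay("cod"))
#' fit <- fitQpcr(plate, config = mcmcConfig(seed = 1))
#' estimates(fit)
#' }
#' @export
fitQpcr <- function(records, priors = qpcrPriors(), config = mcmcConfig(),
                    mode = c("two_step", "continuous_only"),
                    fixedParams = NULL, detectThreshold = 1e-3,
                    includeControls = FALSE) {
  mode <- match.arg(mode)
  if (length(unique(records$assay_id)) != 1L)
    stop("fitQpcr fits one assay at a time; split records by assay_id")
  if (!"detected" %in% names(records)) records$detected <- !is.na(records$ct)
  if (includeControls) {
    records$sample_type[records$sample_type == "negative_control"] <- "unknown"
  } else {
    records <- records[records$sample_type != "negative_control", ,
                       drop = FALSE]
  }
  fixed <- !is.null(fixedParams)
  if (fixed) stopifnot(is(fixedParams, "QpcrParams"))
  std <- records[records$sample_type == "standard", , drop = FALSE]
  unk <- records[records$sample_type == "unknown", , drop = FALSE]
  if (!fixed) {
    if (length(unique(std$nominal_conc)) < 2L)
      stop("need standards at >= 2 distinct concentrations")
    if (!any(std$detected))
      stop("all standard reactions are non-detect; calibration curve ",
           "is unidentifiable")
  }
  notes <- character(0)

  unkIds <- unique(unk$sample_id)
  iu <- match(unk$sample_id, unkIds)
  stdDet <- std$detected
  unkDet <- unk$detected
  counts <- list(ns = nrow(std), nsd = sum(stdDet), nu = length(unkIds),
                 nuw = nrow(unk), nud = sum(unkDet))
  data <- list()
  if (mode == "two_step") {
    if (counts$ns > 0L) {
      data$cs <- log10(std$nominal_conc)
      data$zs <- as.integer(stdDet)
    }
    if (counts$nuw > 0L) {
      data$iu <- iu
      data$zu <- as.integer(unkDet)
    }
  }
  if (counts$nsd > 0L) {
    data$csd <- log10(std$nominal_conc[stdDet])
    data$ysd <- std$ct[stdDet]
  }
  if (counts$nud > 0L) {
    data$iud <- iu[unkDet]
    data$yud <- unk$ct[unkDet]
  }
  if (fixed) {
    data$beta0 <- fixedParams@beta0
    data$beta1 <- fixedParams@beta1
    data$gamma0 <- fixedParams@gamma0
    data$gamma1 <- fixedParams@gamma1
    if (mode == "two_step") {
      data$phi0 <- fixedParams@phi0
      data$phi1 <- fixedParams@phi1
    }
  }

  # Centering constants for the sampled intercept/slope pairs: the Ct line
  # is centered at the mean detected-standard concentration; the detection
  # pair at the Bernoulli-information-weighted mean, theta * (1 - theta)
  # evaluated on the prior-mean logistic, which sits near the 50%-detection
  # concentration where all the slope information lives.
  inits <- list()
  if (!fixed) {
    cs0 <- log10(std$nominal_conc)
    data$cbar <- mean(cs0[stdDet])
    if (mode == "two_step") {
      th0 <- stats::plogis(priors$phi0$mu + priors$phi1$mu * cs0)
      wphi <- th0 * (1 - th0)
      data$cbarPhi <- sum(wphi * cs0) / sum(wphi)
      inits$phi1 <- max(priors$phi1$mu, 0.5)
      inits$phiC <- priors$phi0$mu + inits$phi1 * data$cbarPhi
    }
    inits$beta1 <- min(priors$beta1$mu, -0.5)
    inits$betaC <- priors$beta0$mu + inits$beta1 * data$cbar
    inits$gamma1 <- priors$gamma1$mu
    inits$gammaC <- priors$gamma0$mu + inits$gamma1 * data$cbar
  }
  if (counts$nu > 0L) {
    inits$lc <- vapply(unkIds, function(s) {
      cts <- unk$ct[unk$sample_id == s & unkDet]
      if (length(cts) == 0L) return(-3)
      est <- (mean(cts) - priors$beta0$mu) / priors$beta1$mu
      min(max(est, -6), 8)
    }, numeric(1), USE.NAMES = FALSE)
  }

  monitor <- character(0)
  if (!fixed) {
    monitor <- c(if (mode == "two_step") c("phi0", "phi1"),
                 "beta0", "beta1", "gamma0", "gamma1")
  }
  if (counts$nu > 0L) monitor <- c(monitor, "lc")
  if (!length(monitor))
    stop("nothing to estimate: parameters fixed and no unknown samples")

  modelString <- .qpcrModelString(priors, mode, fixed, counts)
  draws <- .runJags(modelString, data, inits, monitor, config)

  # rename lc[j] -> log10C[<sample_id>]
  latents <- character(0)
  if (counts$nu > 0L) {
    lcCols <- sprintf("lc[%d]", seq_along(unkIds))
    if (counts$nu == 1L && "lc" %in% colnames(draws[[1]])) lcCols <- "lc"
    newNames <- sprintf("log10C[%s]", unkIds)
    draws <- lapply(draws, function(m) {
      cn <- colnames(m)
      cn[match(lcCols, cn)] <- newNames
      colnames(m) <- cn
      m
    })
    latents <- stats::setNames(unkIds, newNames)
  }
  diag <- .mcmcDiagnostics(draws)
  if (!diag$converged)
    notes <- c(notes, "convergence diagnostics failed (rhat/ess)")

  priorDriven <- character(0)
  if (mode == "continuous_only" && counts$nu > 0L) {
    nDet <- tapply(unkDet, unk$sample_id, sum)
    priorDriven <- names(nDet)[nDet == 0L]
    if (length(priorDriven))
      notes <- c(notes, paste0("prior-driven (no detected replicates): ",
                               paste(priorDriven, collapse = ", ")))
  }
  est <- .buildEstimates(draws, latents, records$assay_id[1L],
                         if (mode == "two_step") "qpcr_two_step"
                         else "qpcr_continuous",
                         detectThreshold, priorDriven)
  new("PcrFit", platform = "qpcr", mode = mode, draws = draws,
      nChains = config$nChains, nIter = config$nIter,
      rhat = diag$rhat, ess = diag$ess, converged = diag$converged,
      seed = config$seed, estimates = est, notes = notes)
}
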