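# Binomial/cloglog ddPCR model: positive-droplet counts are binomial in
# the total droplets with a success probability tied to log10 concentration
# through the complementary log-log link, so technical replicates of a
# sample pool their droplets through one shared latent concentration.

#' Complementary log-log transform and its inverse
#'
#' `cloglog(p) = log(-log(1 - p))`; its inverse is
#' `1 - exp(-exp(x))`. The cloglog link linearises the Poisson-occupancy
#' relationship between the positive-droplet fraction and log
#' concentration: `log(C) = cloglog(omega) - log(V)` for droplet volume V.
#'
#' @param p probabilities strictly inside (0, 1).
#' @param x real values.
#' @return transformed values; `invCloglog(cloglog(p))` returns `p` to
#'   near machine precision.
#' @examples
#' cloglog(1 - exp(-1))   # 0
#' invCloglog(0)          # 1 - exp(-1)
#' @export
cloglog <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("cloglog is defined for probabilities strictly inside (0, 1)")
  log(-log1p(-p))
}

#' @rdname cloglog
#' @export
invCloglog <- function(x) -expm1(-exp(x))

#' Single-well Poisson concentration estimate
#'
#' The default ddPCR software formula: `C = -log(1 - W/U) / V`, the
#' Poisson-partitioning estimate from one well's positive-droplet fraction.
#' Returns 0 when no droplet is positive; a saturated well (`W = U`) has no
#' finite estimate and is an error.
#'
#' @param W positive droplet count(s).
#' @param U total droplet count(s).
#' @param V droplet volume, microlitres.
#' @return concentration(s) in copies/uL.
#' @examples
#' poissonEstimate(W = 169, U = 18650, V = 0.00085)
#' @export
poissonEstimate <- function(W, U, V) {
  stopifnot(all(U >= 1), all(W >= 0), all(W <= U), all(V > 0))
  if (any(W == U))
    stop("saturated well (W = U): concentration estimate is infinite; ",
         "dilute or drop the well")
  -log1p(-W / U) / V
}

#' Log-likelihood of the binomial/cloglog ddPCR model
#'
#' Sums the binomial log-pmf of each well's positive-droplet count `W`
#' given its total `U` and the success probability
#' `omega = invCloglog(kappa0 + kappa1 * log10(C))`, with one shared
#' log10(C) per sample (standards at their nominal concentration, unknowns
#' at the latent value supplied). Negative-control records are excluded.
#'
#' @param params a [DdpcrParams-class].
#' @param log10_c_by_sample named numeric vector of latent log10
#'   concentrations per unknown `sample_id`.
#' @param records droplet records (see [readDdpcrTable()]).
#' @return the scalar log-likelihood.
#' @export
ddpcrLogLikelihood <- function(params, log10_c_by_sample, records) {
  stopifnot(is(params, "DdpcrParams"))
  records <- records[records$sample_type != "negative_control", , drop = FALSE]
  c_vec <- .recordLog10C(records, log10_c_by_sample)
  omega <- invCloglog(params@kappa0 + params@kappa1 * c_vec)
  sum(stats::dbinom(records$positive_droplets, records$total_droplets,
                    omega, log = TRUE))
}

#' Priors for the ddPCR calibration model
#'
#' Defaults centred on the manufacturer droplet volume
#' (`kappa0 ~ Normal(log(0.00085), 1)`) and 100% assay efficiency
#' (`kappa1 ~ Normal(log(10), 0.5)`, truncated positive), wide enough to
#' expose an assay whose fitted intercept implies a different effective
#' droplet volume.
#'
#' @param kappa0,kappa1,log10C each a `list(mu =, sd =)` Normal prior.
#' @return a named list of prior specifications.
#' @export
ddpcrPriors <- function(kappa0 = list(mu = log(0.00085), sd = 1),
                        kappa1 = list(mu = log(10), sd = 0.5),
                        log10C = list(mu = 0, sd = 3)) {
  pr <- list(kappa0 = kappa0, kappa1 = kappa1, log10C = log10C)
  ok <- vapply(pr, function(p) is.numeric(p$mu) && is.numeric(p$sd) &&
                 is.finite(p$mu) && is.finite(p$sd) && p$sd > 0, TRUE)
  if (!all(ok))
    stop("invalid prior specification for: ",
         paste(names(pr)[!ok], collapse = ", "))
  pr
}

.ddpcrModelString <- function(priors, fixed, counts) {
  lines <- "model {\n"
  if (!fixed)
    lines <- c(lines,
      .centeredPairText("kappa", priors$kappa0, priors$kappa1, lower = 0))
  if (counts$nu > 0L)
    lines <- c(lines, sprintf(
      "  for (j in 1:%d) { lc[j] ~ dnorm(%.17g, %.17g) }\n",
      counts$nu, priors$log10C$mu, 1 / priors$log10C$sd^2))
  if (counts$ns > 0L)
    lines <- c(lines, sprintf(paste0(
      "  for (r in 1:%d) {\n",
      "    ps[r] <- min(0.999999999999, 1 - exp(-exp(kappa0 + kappa1 * cs[r])))\n",
      "    ws[r] ~ dbin(ps[r], us[r])\n",
      "  }\n"), counts$ns))
  if (counts$nuw > 0L)
    lines <- c(lines, sprintf(paste0(
      "  for (r in 1:%d) {\n",
      "    pu[r] <- min(0.999999999999, 1 - exp(-exp(kappa0 + kappa1 * lc[iu[r]])))\n",
      "    wu[r] ~ dbin(pu[r], uu[r])\n",
      "  }\n"), counts$nuw))
  paste0(c(lines, "}\n"), collapse = "")
}

#' Fit the Bayesian ddPCR quantification model
#'
#' Estimates the cloglog intercept and slope from the standard dilution
#' series and, jointly, the latent log10 concentration of every unknown
#' sample, aggregating each sample's technical replicates through its
#' single latent concentration. Saturated wells (`W = U`) are excluded
#' from the likelihood with a warning.
#'
#' @param records droplet records for a single assay (from
#'   [readDdpcrTable()] or [simulateDdpcr()]).
#' @param priors from [ddpcrPriors()].
#' @param config from [mcmcConfig()].
#' @param fixedParams optional [DdpcrParams-class] holding the calibration
#'   line fixed (oracle checks).
#' @param detectThreshold posterior-median concentration below which a
#'   sample is classified non-detect; default 1e-3 copies/uL.
#' @param includeControls treat negative-control wells as unknowns.
#' @return a [PcrFit-class] with `method = "ddpcr"` estimates.
#' @examples
#' \donttest{
#' plate <- simulateDdpcr(defaultDdpcrParams(),
#'                        updateDesign(defaultDesign("ddpcr"), nUnknown = 5L),
#'                        PcrAssay("cod"))
#' fit <- fitDdpcr(plate, config = mcmcConfig(seed = 1))
#' estimates(fit)
#' }
#' @export
fitDdpcr <- function(records, priors = ddpcrPriors(), config = mcmcConfig(),
                     fixedParams = NULL, detectThreshold = 1e-3,
                     includeControls = FALSE) {
  if (length(unique(records$assay_id)) != 1L)
    stop("fitDdpcr fits one assay at a time; split records by assay_id")
  if (includeControls) {
    records$sample_type[records$sample_type == "negative_control"] <- "unknown"
  } else {
    records <- records[records$sample_type != "negative_control", ,
                       drop = FALSE]
  }
  notes <- character(0)
  sat <- records$positive_droplets == records$total_droplets
  if (any(sat)) {
    warning(sum(sat), " saturated well(s) (W = U) excluded from the fit")
    notes <- c(notes, sprintf("%d saturated well(s) excluded", sum(sat)))
    records <- records[!sat, , drop = FALSE]
  }
  fixed <- !is.null(fixedParams)
  if (fixed) stopifnot(is(fixedParams, "DdpcrParams"))
  std <- records[records$sample_type == "standard", , drop = FALSE]
  unk <- records[records$sample_type == "unknown", , drop = FALSE]
  if (!fixed) {
    if (length(unique(std$nominal_conc)) < 2L)
      stop("need standards at >= 2 distinct concentrations")
    if (all(std$positive_droplets == 0L))
      stop("all standard wells have zero positive droplets; calibration ",
           "line is unidentifiable")
  }

  unkIds <- unique(unk$sample_id)
  iu <- match(unk$sample_id, unkIds)
  counts <- list(ns = nrow(std), nu = length(unkIds), nuw = nrow(unk))

  data <- list()
  if (counts$ns > 0L) {
    data$cs <- log10(std$nominal_conc)
    data$ws <- std$positive_droplets
    data$us <- std$total_droplets
  }
  if (counts$nuw > 0L) {
    data$iu <- iu
    data$wu <- unk$positive_droplets
    data$uu <- unk$total_droplets
  }
  if (fixed) {
    data$kappa0 <- fixedParams@kappa0
    data$kappa1 <- fixedParams@kappa1
  }

  # Center the sampled intercept at the information-weighted mean standard
  # concentration: per-well Fisher information for the cloglog-binomial is
  # U * t^2 exp(-t) / (1 - exp(-t)) with t the expected copies per droplet,
  # evaluated at the prior-mean calibration line. This decorrelates the
  # intercept/slope updates far better than the arithmetic mean, because
  # nearly all slope information sits near the saturation knee.
  inits <- list()
  if (!fixed) {
    cs0 <- log10(std$nominal_conc)
    tw <- exp(priors$kappa0$mu + priors$kappa1$mu * cs0)
    wts <- std$total_droplets * tw^2 * exp(-tw) / -expm1(-tw)
    data$cbar <- sum(wts * cs0) / sum(wts)
    inits$kappa1 <- max(priors$kappa1$mu, 0.5)
    inits$kappaC <- priors$kappa0$mu + inits$kappa1 * data$cbar
  }
  if (counts$nu > 0L) {
    inits$lc <- vapply(unkIds, function(s) {
      sel <- unk$sample_id == s
      ratio <- sum(unk$positive_droplets[sel]) / sum(unk$total_droplets[sel])
      if (ratio <= 0) return(-3)
      if (ratio >= 1) return(6)
      est <- (cloglog(ratio) - priors$kappa0$mu) / priors$kappa1$mu
      min(max(est, -6), 8)
    }, numeric(1), USE.NAMES = FALSE)
  }

  monitor <- c(if (!fixed) c("kappa0", "kappa1"),
               if (counts$nu > 0L) "lc")
  if (!length(monitor))
    stop("nothing to estimate: parameters fixed and no unknown samples")

  modelString <- .ddpcrModelString(priors, fixed, counts)
  draws <- .runJags(modelString, data, inits, monitor, config)

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
  est <- .buildEstimates(draws, latents, records$assay_id[1L], "ddpcr",
                         detectThreshold)
  new("PcrFit", platform = "ddpcr", mode = "binomial_cloglog", draws = draws,
      nChains = config$nChains, nIter = config$nIter,
      rhat = diag$rhat, ess = diag$ess, converged = diag$converged,
      seed = config$seed, estimates = est, notes = notes)
}

#' Droplet-volume diagnostic from the cloglog intercept
#'
#' For a 100%-efficient assay the cloglog intercept equals the log droplet
#' volume, so `exp(kappa0)` is the droplet volume (in microlitres) implied
#' by the fitted calibration line. An implied volume far from the
#' manufacturer value signals degraded standards or anomalous droplet
#' chemistry for that assay.
#'
#' @param kappa0 fitted cloglog intercept(s).
#' @return implied droplet volume(s), microlitres.
#' @examples
#' dropletVolumeFromIntercept(-7.07)  # ~0.00085
#' @export
dropletVolumeFromIntercept <- function(kappa0) {
  stopifnot(all(is.finite(kappa0)))
  exp(kappa0)
}

#' Assay-efficiency diagnostic from the cloglog slope
#'
#' The cloglog slope equals `log(10)` when the assay converts template to
#' positive droplets with 100% efficiency; `kappa1 / log(10)` is therefore
#' a dimensionless efficiency ratio (1 for a perfect assay).
#'
#' @param kappa1 fitted cloglog slope(s).
#' @return efficiency ratio(s).
#' @examples
#' efficiencyFromSlope(log(10))  # 1
#' @export
efficiencyFromSlope <- function(kappa1) {
  stopifnot(all(is.finite(kappa1)))
  kappa1 / log(10)
}
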