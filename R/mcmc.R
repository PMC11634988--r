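# Shared MCMC plumbing: sampler configuration, JAGS driver, convergence
# diagnostics and the per-sample estimate table. All fitters run >= 4
# chains with explicitly seeded per-chain RNGs so that the same seed and
# data reproduce the draws exactly.

#' MCMC sampler configuration
#'
#' @param nChains number of chains (>= 2; 4 by default).
#' @param nAdapt adaptation iterations.
#' @param nBurnin burn-in iterations discarded after adaptation.
#' @param nIter retained post-warmup iterations per chain (default 2000).
#' @param seed integer master seed; chain c uses `seed + c`.
#' @return a list with class `"mcmcConfig"`.
#' @export
mcmcConfig <- function(nChains = 4L, nAdapt = 500L, nBurnin = 500L,
                       nIter = 2000L, seed = 1L) {
  cfg <- list(nChains = as.integer(nChains), nAdapt = as.integer(nAdapt),
              nBurnin = as.integer(nBurnin), nIter = as.integer(nIter),
              seed = as.integer(seed))
  stopifnot(cfg$nChains >= 2L, cfg$nIter >= 1L, cfg$nAdapt >= 0L,
            cfg$nBurnin >= 0L)
  class(cfg) <- "mcmcConfig"
  cfg
}

# Runs a JAGS model and returns an mcmc.list of the monitored nodes.
.runJags <- function(modelString, data, inits, monitor, config) {
  initsList <- lapply(seq_len(config$nChains), function(ch) {
    c(inits, list(.RNG.name = "base::Mersenne-Twister",
                  .RNG.seed = config$seed + ch))
  })
  model <- rjags::jags.model(textConnection(modelString), data = data,
                             inits = initsList, n.chains = config$nChains,
                             n.adapt = config$nAdapt, quiet = TRUE)
  if (config$nBurnin > 0L)
    update(model, n.iter = config$nBurnin, progress.bar = "none")
  rjags::coda.samples(model, variable.names = monitor,
                      n.iter = config$nIter, progress.bar = "none")
}

# Split-free rhat (potential scale reduction) and per-parameter effective
# sample size, computed with coda.
.mcmcDiagnostics <- function(draws) {
  pars <- colnames(draws[[1]])
  keep <- vapply(pars, function(p) {
    v <- unlist(lapply(draws, function(m) m[, p]))
    stats::var(v) > 0
  }, TRUE)
  rhat <- rep(NA_real_, length(pars))
  names(rhat) <- pars
  if (sum(keep) > 0L && length(draws) >= 2L) {
    sub <- lapply(draws, function(m) coda::as.mcmc(m[, keep, drop = FALSE]))
    gd <- coda::gelman.diag(coda::as.mcmc.list(sub), autoburnin = FALSE,
                            multivariate = FALSE)
    rhat[keep] <- gd$psrf[, 1L]
  }
  ess <- coda::effectiveSize(coda::as.mcmc.list(
    lapply(draws, coda::as.mcmc)))
  ess <- ess[pars]
  names(ess) <- pars
  converged <- !any(keep) ||
    (all(is.finite(rhat[keep])) && max(rhat[keep]) < 1.05 &&
       min(ess[keep]) >= 400)
  list(rhat = rhat, ess = ess, converged = converged)
}

# Builds the per-sample estimate table from latent log10 C draws.
# `latents` maps monitored column name -> sample_id.
.buildEstimates <- function(draws, latents, assay_id, method,
                            detectThreshold = 1e-3,
                            priorDriven = character(0)) {
  if (!length(latents)) {
    return(data.frame(sample_id = character(0), assay_id = character(0),
                      method = character(0), log10_c_median = numeric(0),
                      log10_c_mean = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), ci_width = numeric(0),
                      is_detect = logical(0), prior_driven = logical(0)))
  }
  mat <- do.call(rbind, lapply(draws, function(m)
    m[, names(latents), drop = FALSE]))
  q <- apply(mat, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  med <- q[2L, ]
  data.frame(
    sample_id = unname(latents),
    assay_id = assay_id,
    method = method,
    log10_c_median = unname(med),
    log10_c_mean = unname(colMeans(mat)),
    ci_low = unname(q[1L, ]),
    ci_high = unname(q[3L, ]),
    ci_width = unname(q[3L, ] - q[1L, ]),
    is_detect = unname(10^med >= detectThreshold),
    prior_driven = unname(latents) %in% priorDriven,
    row.names = NULL)
}

# Normal prior spec helper: list(mu, sd) -> JAGS dnorm(mu, tau) text.
.dnormText <- function(name, prior, lower = NULL, upper = NULL) {
  tau <- 1 / prior$sd^2
  trunc <- if (!is.null(lower)) sprintf(" T(%s,)", lower)
           else if (!is.null(upper)) sprintf(" T(,%s)", upper)
           else ""
  sprintf("  %s ~ dnorm(%.17g, %.17g)%s\n", name, prior$mu, tau, trunc)
}
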