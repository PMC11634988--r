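#' @rdname PcrAssay-class
#' @param object,x a `PcrAssay`, `QpcrParams`, `DdpcrParams` or `PcrFit`.
#' @export
setGeneric("assayId", function(x) standardGeneric("assayId"))

#' @rdname PcrAssay-class
#' @export
setMethod("assayId", "PcrAssay", function(x) x@assayId)

#' Posterior draws of a fit
#'
#' @param x a [PcrFit-class].
#' @param pars optional character vector of parameter names to keep.
#' @param collapse if TRUE (default) chains are stacked into one matrix
#'   with an attribute `chain`; otherwise the underlying
#'   [coda::mcmc.list] is returned.
#' @return a numeric matrix (draws x parameters) or an `mcmc.list`.
#' @export
setGeneric("posteriorDraws",
           function(x, pars = NULL, collapse = TRUE)
             standardGeneric("posteriorDraws"))

#' @rdname posteriorDraws
#' @export
setMethod("posteriorDraws", "PcrFit", function(x, pars = NULL,
                                               collapse = TRUE) {
  dr <- x@draws
  if (!is.null(pars)) {
    keep <- colnames(dr[[1]]) %in% pars
    if (!any(keep)) stop("none of the requested parameters were monitored")
    dr <- lapply(dr, function(m) m[, keep, drop = FALSE])
  }
  if (!collapse) return(coda::as.mcmc.list(lapply(dr, coda::as.mcmc)))
  mat <- do.call(rbind, lapply(dr, as.matrix))
  attr(mat, "chain") <- rep(seq_along(dr), vapply(dr, nrow, 1L))
  mat
})

#' Per-sample concentration estimates of a fit
#'
#' Returns the estimate table built from the 2.5/50/97.5% posterior
#' quantiles of each unknown sample's latent log10 concentration: columns
#' `sample_id`, `assay_id`, `method`, `log10_c_median`, `log10_c_mean`,
#' `ci_low`, `ci_high`, `ci_width`, `is_detect` (plus `prior_driven` where
#' applicable).
#'
#' @param x a [PcrFit-class].
#' @return a data.frame, one row per unknown sample.
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname estimates
#' @export
setMethod("estimates", "PcrFit", function(x) x@estimates)

#' MCMC convergence diagnostics of a fit
#'
#' @param x a [PcrFit-class].
#' @return data.frame with columns `parameter`, `rhat`, `ess`.
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "PcrFit", function(x) {
  data.frame(parameter = names(x@rhat), rhat = unname(x@rhat),
             ess = unname(x@ess[names(x@rhat)]), row.names = NULL)
})

#' @rdname diagnostics
#' @description `isConverged()` is TRUE only when all monitored parameters
#'   have rhat below 1.05 and effective sample size of at least 400.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname diagnostics
#' @export
setMethod("isConverged", "PcrFit", function(x) x@converged)

setMethod("show", "PcrAssay", function(object) {
  cat("PcrAssay '", object@assayId, "': reaction ",
      object@reactionVolumeUl, " uL, ", object@maxCycles,
      " cycles, droplet ", object@dropletVolumeUl, " uL\n", sep = "")
})

setMethod("show", "QpcrParams", function(object) {
  cat("QpcrParams\n",
      "  detection : phi0 = ", format(object@phi0),
      ", phi1 = ", format(object@phi1), "\n",
      "  Ct mean   : beta0 = ", format(object@beta0),
      ", beta1 = ", format(object@beta1), "\n",
      "  Ct log-sd : gamma0 = ", format(object@gamma0),
      ", gamma1 = ", format(object@gamma1), "\n", sep = "")
})

setMethod("show", "DdpcrParams", function(object) {
  cat("DdpcrParams: kappa0 = ", format(object@kappa0),
      " (droplet volume ", format(exp(object@kappa0), digits = 3),
      " uL), kappa1 = ", format(object@kappa1),
      " (efficiency ", format(object@kappa1 / log(10), digits = 4),
      ")\n", sep = "")
})

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign [", object@platform, "]\n",
      "  standards: ", length(object@standardConcs), " concentrations (",
      format(min(object@standardConcs)), " - ",
      format(max(object@standardConcs)), " copies/uL) x ",
      object@nStandardReps, " reps\n",
      "  unknowns : ",
      if (length(object@unknownLog10Concs))
        length(object@unknownLog10Concs) else object@nUnknown,
      " samples x ", object@nUnknownReps, " reps; ",
      object@nAbsentSamples, " true absences; ",
      object@nNegativeControls, " negative controls\n", sep = "")
  if (object@platform == "ddpcr")
    cat("  droplets : mean ", object@dropletsMean, ", cv ",
        object@dropletsDispersion, "\n", sep = "")
})

setMethod("show", "PcrFit", function(object) {
  cat("PcrFit [", object@platform,
      if (nzchar(object@mode)) paste0("/", object@mode), "]: ",
      object@nChains, " chains x ", object@nIter, " draws, seed ",
      object@seed, "\n", sep = "")
  cat("  converged: ", object@converged,
      " (max rhat ", format(max(object@rhat), digits = 4),
      ", min ess ", format(min(object@ess), digits = 4), ")\n", sep = "")
  if (nrow(object@estimates))
    cat("  estimates: ", nrow(object@estimates), " samples\n", sep = "")
  if (length(object@notes))
    cat("  notes: ", paste(object@notes, collapse = "; "), "\n", sep = "")
})
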