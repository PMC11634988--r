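# Standalone logistic sensitivity analysis: the Bernoulli/logistic
# detection model fitted to standards alone, used to compare detection
# probability between platforms across the concentration range.

#' Extract binary detection outcomes from plate records
#'
#' Converts standard-sample records into the (log10 concentration,
#' detected) pairs the sensitivity model consumes. qPCR records are
#' detected when a Ct was recorded; ddPCR records when the well has at
#' least `dropletThreshold` positive droplets (default 1, the
#' single-positive-droplet rule).
#'
#' @param records qPCR or ddPCR records (standards are used; other rows
#'   are ignored because their true concentration is unknown).
#' @param dropletThreshold minimum positive droplets that counts as a
#'   ddPCR detection.
#' @return data.frame with columns `assay_id`, `sample_id`, `log10_c`,
#'   `detected`.
#' @export
detectionOutcomes <- function(records, dropletThreshold = 1L) {
  std <- records[records$sample_type == "standard", , drop = FALSE]
  if (nrow(std) == 0L) stop("no standard records found")
  detected <- if ("positive_droplets" %in% names(std))
    std$positive_droplets >= dropletThreshold
  else if ("detected" %in% names(std)) std$detected
  else !is.na(std$ct)
  data.frame(assay_id = std$assay_id, sample_id = std$sample_id,
             log10_c = log10(std$nominal_conc), detected = detected,
             row.names = NULL)
}

#' Fit the logistic detection-probability model
#'
#' Bayesian logistic regression of binary detection on log10 nominal
#' concentration: `Z ~ Bernoulli(plogis(phi0 + phi1 * log10_c))`. Works
#' identically for qPCR outcomes (Ct recorded or not) and ddPCR outcomes
#' (positive droplets above a threshold); see [detectionOutcomes()].
#'
#' @param outcomes data.frame with columns `log10_c` and logical
#'   `detected` (as from [detectionOutcomes()]); must span at least two
#'   distinct concentrations.
#' @param priors from [qpcrPriors()]; only the `phi0`/`phi1` entries are
#'   used (one detection model, two entry points).
#' @param config from [mcmcConfig()].
#' @return a [PcrFit-class] with draws for `phi0` and `phi1`. When every
#'   outcome is identical (all detected or none) the data carry no slope
#'   information; the fit is returned prior-dominated with a note.
#' @export
fitDetectionLogistic <- function(outcomes, priors = qpcrPriors(),
                                 config = mcmcConfig()) {
  stopifnot(all(c("log10_c", "detected") %in% names(outcomes)))
  if (length(unique(outcomes$log10_c)) < 2L)
    stop("detection outcomes from a single concentration cannot identify ",
         "the logistic curve")
  notes <- character(0)
  if (length(unique(outcomes$detected)) == 1L) {
    notes <- c(notes, paste0(
      "all outcomes identical (",
      if (outcomes$detected[1L]) "detected" else "non-detect",
      "); posterior is prior-dominated"))
  }
  modelString <- paste0(
    "model {\n",
    .centeredPairText("phi", priors$phi0, priors$phi1, lower = 0),
    sprintf("  for (r in 1:%d) { z[r] ~ dbern(ilogit(phi0 + phi1 * c[r])) }\n",
            nrow(outcomes)),
    "}\n")
  data <- list(z = as.integer(outcomes$detected), c = outcomes$log10_c,
               cbar = mean(outcomes$log10_c))
  inits <- list(phi1 = max(priors$phi1$mu, 0.5))
  inits$phiC <- priors$phi0$mu + inits$phi1 * data$cbar
  draws <- .runJags(modelString, data, inits, c("phi0", "phi1"), config)
  diag <- .mcmcDiagnostics(draws)
  if (!diag$converged)
    notes <- c(notes, "convergence diagnostics failed (rhat/ess)")
  new("PcrFit", platform = "detection", mode = "logistic", draws = draws,
      nChains = config$nChains, nIter = config$nIter,
      rhat = diag$rhat, ess = diag$ess, converged = diag$converged,
      seed = config$seed,
      estimates = data.frame(), notes = notes)
}

#' Concentration of 50% detection probability
#'
#' Solves `plogis(phi0 + phi1 * log10_c) = 0.5`, i.e.
#' `10^(-phi0 / phi1)` copies/uL — the point often quoted when comparing
#' platform sensitivity.
#'
#' @param phi0,phi1 logistic intercept and slope (`phi1` must be nonzero).
#' @return concentration(s) in copies/uL.
#' @examples
#' c50(4.605, 2.3025)  # ~1e-2
#' @export
c50 <- function(phi0, phi1) {
  if (any(phi1 == 0)) stop("c50 undefined for phi1 = 0 (flat curve)")
  10^(-phi0 / phi1)
}

#' Posterior detection curve over a concentration grid
#'
#' Evaluates the detection probability at each grid point for every
#' posterior draw of (phi0, phi1) and summarises the pointwise posterior
#' by its median and central 95% credible band.
#'
#' @param fit a [PcrFit-class] from [fitDetectionLogistic()] (or any fit
#'   monitoring `phi0`/`phi1`).
#' @param grid strictly increasing log10 concentrations; the default spans
#'   the range where platform sensitivities typically differ.
#' @param assay_id,method labels carried into the output table.
#' @return data.frame with columns `assay_id`, `method`, `log10_c`,
#'   `theta`, `theta_low`, `theta_high`; the per-draw curve matrix is
#'   attached as `attr(x, "theta_draws")` for paired comparisons.
#' @export
detectionCurve <- function(fit, grid = seq(-3, 2, by = 0.1),
                           assay_id = "assay", method = fit@platform) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  dr <- posteriorDraws(fit, pars = c("phi0", "phi1"))
  theta <- stats::plogis(outer(dr[, "phi0"], rep(1, length(grid))) +
                           outer(dr[, "phi1"], grid))
  q <- apply(theta, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  out <- data.frame(assay_id = assay_id, method = method, log10_c = grid,
                    theta = q[2L, ], theta_low = q[1L, ],
                    theta_high = q[3L, ], row.names = NULL)
  attr(out, "theta_draws") <- theta
  out
}

#' Pointwise difference of two detection curves
#'
#' Computes `theta_a - theta_b` at every grid point, with the credible
#' band propagated by differencing paired posterior draws (draw i of curve
#' a minus draw i of curve b). Positive values mean method a detects with
#' higher probability. Antisymmetric: `detectionDifference(a, b)` equals
#' the negation of `detectionDifference(b, a)`.
#'
#' @param curve_a,curve_b detection curves from [detectionCurve()]
#'   evaluated on identical grids (draw matrices attached).
#' @return data.frame with columns `log10_c`, `delta_theta`,
#'   `delta_low`, `delta_high`.
#' @export
detectionDifference <- function(curve_a, curve_b) {
  if (!isTRUE(all.equal(curve_a$log10_c, curve_b$log10_c)))
    stop("detection curves must share an identical grid")
  da <- attr(curve_a, "theta_draws")
  db <- attr(curve_b, "theta_draws")
  if (is.null(da) || is.null(db))
    stop("curves must carry their posterior draws (built by detectionCurve)")
  n <- min(nrow(da), nrow(db))
  d <- da[seq_len(n), , drop = FALSE] - db[seq_len(n), , drop = FALSE]
  q <- apply(d, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  data.frame(log10_c = curve_a$log10_c, delta_theta = q[2L, ],
             delta_low = q[1L, ], delta_high = q[3L, ], row.names = NULL)
}
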