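# Precision and detection comparisons: credible-interval widths on the
# log10 scale ("orders of magnitude"), paired method contrasts, and the
# two-step vs continuous-only ablation. All operations are pure functions
# of their estimate tables.

#' Credible-interval width table
#'
#' One row per sample with the posterior median and the width of the 95%
#' credible interval of log10 concentration — the operational measure of
#' quantification precision (in orders of magnitude).
#'
#' @param est estimate table (see [estimates()]).
#' @return data.frame with columns `sample_id`, `assay_id`, `method`,
#'   `log10_c_median`, `ci_width`.
#' @export
ciWidthTable <- function(est) {
  .checkColumns(est, c("sample_id", "ci_low", "ci_high"), "estimate")
  data.frame(sample_id = est$sample_id, assay_id = est$assay_id,
             method = est$method, log10_c_median = est$log10_c_median,
             ci_width = est$ci_high - est$ci_low, row.names = NULL)
}

#' Pairwise method comparison of estimates
#'
#' Joins two estimate tables on `sample_id` and computes, per sample, the
#' difference in credible-interval width (`delta_width = width_a -
#' width_b`) and posterior median (`delta_median`). Positive
#' `delta_width` means method a is less precise for that sample. A
#' decade-binned stratum summary (by the mean of the two medians) is
#' attached as `attr(x, "strata")`.
#'
#' @param est_a,est_b estimate tables covering a common set of samples.
#' @return data.frame with columns `sample_id`, `method_a`, `method_b`,
#'   `median_a`, `median_b`, `delta_median`, `width_a`, `width_b`,
#'   `delta_width`.
#' @export
compareMethods <- function(est_a, est_b) {
  common <- intersect(est_a$sample_id, est_b$sample_id)
  if (length(common) == 0L)
    stop("the two estimate tables share no sample_id")
  a <- est_a[match(common, est_a$sample_id), ]
  b <- est_b[match(common, est_b$sample_id), ]
  out <- data.frame(
    sample_id = common,
    method_a = a$method, method_b = b$method,
    median_a = a$log10_c_median, median_b = b$log10_c_median,
    delta_median = a$log10_c_median - b$log10_c_median,
    width_a = a$ci_high - a$ci_low, width_b = b$ci_high - b$ci_low,
    delta_width = (a$ci_high - a$ci_low) - (b$ci_high - b$ci_low),
    row.names = NULL)
  mid <- (out$median_a + out$median_b) / 2
  bin <- cut(mid, breaks = c(-Inf, seq(-3, 6, by = 1), Inf))
  strata <- stats::aggregate(
    cbind(delta_width = out$delta_width, delta_median = out$delta_median),
    by = list(stratum = bin), FUN = mean)
  strata$n <- as.vector(table(bin)[as.character(strata$stratum)])
  attr(out, "strata") <- strata
  out
}

#' Classify samples as detect / non-detect
#'
#' A sample is a non-detect when its posterior median concentration falls
#' below `threshold` (default 1e-3 copies/uL); a median exactly at the
#' threshold counts as a detect.
#'
#' @param est estimate table.
#' @param threshold non-detect threshold, copies/uL.
#' @return list with `table` (per-sample `sample_id`, `method`,
#'   `is_detect`) and `counts` (per-method detect / non-detect totals).
#' @export
classifyDetects <- function(est, threshold = 1e-3) {
  .checkColumns(est, c("sample_id", "method", "log10_c_median"), "estimate")
  tab <- data.frame(sample_id = est$sample_id, method = est$method,
                    is_detect = 10^est$log10_c_median >= threshold,
                    row.names = NULL)
  counts <- stats::aggregate(
    cbind(n_detect = tab$is_detect, n_nondetect = !tab$is_detect),
    by = list(method = tab$method), FUN = sum)
  list(table = tab, counts = counts)
}

#' Precision gain of the two-step qPCR model
#'
#' Fits the two-step and continuous-only qPCR models on the same records
#' with the same seed and returns the per-sample difference in
#' credible-interval width, `delta_width = width_continuous -
#' width_two_step`. Positive values identify samples for which the
#' detection component tightens the posterior; the gain concentrates at
#' low concentrations and vanishes as templates become abundant.
#'
#' @inheritParams fitQpcr
#' @return data.frame with columns `sample_id`, `width_two_step`,
#'   `width_continuous`, `delta_width`, `median_two_step`,
#'   `median_continuous`, plus the two [PcrFit-class] objects attached as
#'   `attr(x, "fits")`.
#' @export
twoStepGain <- function(records, priors = qpcrPriors(),
                        config = mcmcConfig(), detectThreshold = 1e-3) {
  fit2 <- fitQpcr(records, priors, config, mode = "two_step",
                  detectThreshold = detectThreshold)
  fitC <- fitQpcr(records, priors, config, mode = "continuous_only",
                  detectThreshold = detectThreshold)
  cmp <- compareMethods(estimates(fitC), estimates(fit2))
  out <- data.frame(sample_id = cmp$sample_id,
                    width_two_step = cmp$width_b,
                    width_continuous = cmp$width_a,
                    delta_width = cmp$delta_width,
                    median_two_step = cmp$median_b,
                    median_continuous = cmp$median_a,
                    row.names = NULL)
  attr(out, "fits") <- list(two_step = fit2, continuous_only = fitC)
  out
}
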