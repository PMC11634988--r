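# Closed-form lower/upper limits of detection and quantification. qPCR's
# floor is one template copy in the pooled reaction volume; ddPCR's limits
# come from one positive (lower) or one negative (upper) droplet among the
# U partitions, through the cloglog form of the Poisson-occupancy model.

#' qPCR lower limit of detection and quantification
#'
#' One DNA copy in the pooled volume of `n_replicates` reactions:
#' `1 / (n_replicates * reaction_volume_ul)` copies/uL. For a single 20 uL
#' reaction this is 0.05 copies/uL (10^-1.3).
#'
#' @param reaction_volume_ul reaction volume, microlitres.
#' @param n_replicates technical replicates pooled.
#' @return limit concentration, copies/uL.
#' @examples
#' qpcrLowerLimit(20)      # 0.05
#' qpcrLowerLimit(20, 4)   # 0.0125
#' @export
qpcrLowerLimit <- function(reaction_volume_ul = 20, n_replicates = 1L) {
  stopifnot(all(reaction_volume_ul > 0), all(n_replicates >= 1))
  1 / (n_replicates * reaction_volume_ul)
}

#' ddPCR lower limit of detection and quantification
#'
#' The concentration at which a single droplet among the pooled total is
#' positive: `exp(cloglog(1 / U_total) - log(V))` with
#' `U_total = n_replicates * total_droplets`. Since each droplet is an
#' independent end-point reaction, adding replicates (or droplets) lowers
#' the limit in direct proportion.
#'
#' @param total_droplets droplets per reaction (U, >= 2).
#' @param droplet_volume_ul droplet volume V, microlitres.
#' @param n_replicates technical replicates pooled.
#' @return limit concentration, copies/uL.
#' @examples
#' ddpcrLowerLimit(20000, 0.00085)  # ~0.059
#' @export
ddpcrLowerLimit <- function(total_droplets = 20000L,
                            droplet_volume_ul = 0.00085,
                            n_replicates = 1L) {
  stopifnot(all(droplet_volume_ul > 0), all(n_replicates >= 1))
  u <- n_replicates * total_droplets
  if (any(total_droplets < 2))
    stop("total_droplets must be >= 2")
  exp(cloglog(1 / u) - log(droplet_volume_ul))
}

#' ddPCR upper limit of detection and quantification
#'
#' The concentration at which all but one droplet is positive:
#' `exp(cloglog((U - 1) / U) - log(V))`. Beyond this point the
#' positive-droplet fraction carries no further information, so unlike
#' qPCR, ddPCR has a quantification ceiling.
#'
#' @param total_droplets droplets in the reaction (U, >= 2).
#' @param droplet_volume_ul droplet volume V, microlitres.
#' @return limit concentration, copies/uL.
#' @examples
#' ddpcrUpperLimit(20000, 0.00085)  # ~1.17e4
#' @export
ddpcrUpperLimit <- function(total_droplets = 20000L,
                            droplet_volume_ul = 0.00085) {
  stopifnot(all(droplet_volume_ul > 0))
  if (any(total_droplets < 2))
    stop("total_droplets must be >= 2")
  exp(cloglog((total_droplets - 1) / total_droplets) -
        log(droplet_volume_ul))
}

#' Detection/quantification limits as a function of replicate number
#'
#' Tabulates the lower (and, for ddPCR, upper) limit for 1 to `n_max`
#' technical replicates. Replicates pool information — droplets for ddPCR,
#' reaction volume for qPCR — so the lower limit decreases as 1/n.
#'
#' @param platform `"qpcr"` or `"ddpcr"`.
#' @param n_max largest replicate count tabulated.
#' @param total_droplets,droplet_volume_ul ddPCR constants.
#' @param reaction_volume_ul qPCR reaction volume.
#' @return data.frame with one row per replicate count and columns
#'   `platform`, `n_replicates`, `total_droplets`, `droplet_volume_ul`,
#'   `reaction_volume_ul`, `c_lt`, `c_ut` (`c_ut` is NA for qPCR, which
#'   has no upper limit).
#' @examples
#' limitVsReplicates("ddpcr", n_max = 5)
#' @export
limitVsReplicates <- function(platform = c("qpcr", "ddpcr"), n_max = 10L,
                              total_droplets = 20000L,
                              droplet_volume_ul = 0.00085,
                              reaction_volume_ul = 20) {
  platform <- match.arg(platform)
  stopifnot(n_max >= 1)
  n <- seq_len(n_max)
  if (platform == "qpcr") {
    clt <- qpcrLowerLimit(reaction_volume_ul, n)
    cut_ <- NA_real_
    total_droplets <- NA_integer_
    droplet_volume_ul <- NA_real_
  } else {
    clt <- ddpcrLowerLimit(total_droplets, droplet_volume_ul, n)
    cut_ <- ddpcrUpperLimit(total_droplets, droplet_volume_ul)
    reaction_volume_ul <- NA_real_
  }
  data.frame(platform = platform, n_replicates = n,
             total_droplets = total_droplets,
             droplet_volume_ul = droplet_volume_ul,
             reaction_volume_ul = reaction_volume_ul,
             c_lt = clt, c_ut = cut_, row.names = NULL)
}
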