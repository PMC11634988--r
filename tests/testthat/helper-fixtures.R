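# Shared fixtures: a reference assay, generator truths, and small designs
# used across the module tests. Everything is built in code at test time.

codAssay <- PcrAssay("cod", reactionVolumeUl = 20, maxCycles = 45L,
                     dropletVolumeUl = 0.00085)

truthQpcr <- defaultQpcrParams()
truthDdpcr <- defaultDdpcrParams()

# A design stripped to the essentials for fast fitter tests.
smallQpcrDesign <- function(seed = 1L, nUnknown = 5L, ...) {
  updateDesign(defaultDesign("qpcr", seed = seed), nUnknown = nUnknown,
               nAbsentSamples = 1L, nNegativeControls = 1L, ...)
}

smallDdpcrDesign <- function(seed = 1L, nUnknown = 5L, ...) {
  updateDesign(defaultDesign("ddpcr", seed = seed), nUnknown = nUnknown,
               nAbsentSamples = 1L, nNegativeControls = 1L, ...)
}

# Short MCMC config for tests that only need a working posterior, not the
# full convergence contract.
quickConfig <- function(seed = 1L, nIter = 1000L) {
  mcmcConfig(nChains = 4L, nAdapt = 300L, nBurnin = 300L, nIter = nIter,
             seed = seed)
}

# Writes records to a temporary CSV and returns the path.
tmpCsv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}
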