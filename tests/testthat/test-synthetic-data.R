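test_that("default designs reproduce the study dilution series", {
  dq <- defaultDesign("qpcr")
  dd <- defaultDesign("ddpcr")
  expect_equal(dq@standardConcs, 10^(-1:6))
  expect_equal(dd@standardConcs, 10^(-3:4))
  expect_length(dd@standardConcs, 8L)
  expect_equal(dq@nStandardReps, 3L)
  expect_equal(dd@nStandardReps, 3L)
  expect_equal(dd@dropletsMean, 20000L)
})

test_that("simulated qPCR detection fractions match the logistic curve", {
  # one standard, many replicates: the empirical detect rate is a binomial
  # proportion whose truth is plogis(phi0 + phi1 * c)
  p <- QpcrParams(0, 2, 38, -3.32, -1.2, 0)
  for (conc in c(1e6, 1)) {
    des <- updateDesign(defaultDesign("qpcr"), standardConcs = conc,
                        nStandardReps = 10000L, nUnknown = 0L,
                        nAbsentSamples = 0L, nNegativeControls = 0L,
                        seed = 5L)
    plate <- simulateQpcr(p, des, codAssay)
    frac <- mean(plate$detected)
    theta <- plogis(0 + 2 * log10(conc))
    se <- sqrt(theta * (1 - theta) / 10000)
    expect_lt(abs(frac - theta), max(3 * se, 1e-4))
  }
})

test_that("simulated detected Ct values match the conditional Normal", {
  p <- QpcrParams(38, 3.32, 38, -3.32, -1.2, 0)  # always-detect regime
  des <- updateDesign(defaultDesign("qpcr"), standardConcs = 1e3,
                      nStandardReps = 10000L, nUnknown = 0L,
                      nAbsentSamples = 0L, nNegativeControls = 0L, seed = 6L)
  plate <- simulateQpcr(p, des, codAssay)
  cts <- plate$ct[plate$detected]
  expect_gt(length(cts), 9000)
  se <- exp(-1.2) / sqrt(length(cts))
  expect_lt(abs(mean(cts) - (38 - 3.32 * 3)), 3 * se)
  expect_lt(abs(sd(cts) - exp(-1.2)), 0.01)
})

test_that("simulated ddPCR positive fractions match the cloglog curve", {
  k <- DdpcrParams(log(0.00085), log(10))
  des <- updateDesign(defaultDesign("ddpcr"), standardConcs = 1e3,
                      nStandardReps = 1000L, nUnknown = 0L,
                      nAbsentSamples = 0L, nNegativeControls = 0L, seed = 7L)
  plate <- simulateDdpcr(k, des, codAssay)
  omega <- 1 - exp(-0.85)
  frac <- sum(plate$positive_droplets) / sum(plate$total_droplets)
  se <- sqrt(omega * (1 - omega) / sum(plate$total_droplets))
  expect_equal(omega, 0.5725851, tolerance = 1e-6)
  expect_lt(abs(frac - omega), 3 * se)
})

test_that("true-absence samples and negative controls never amplify", {
  plate <- simulateQpcr(truthQpcr, smallQpcrDesign(seed = 8L), codAssay)
  absent <- grepl("^(ABS|NTC)", plate$sample_id)
  expect_true(any(absent))
  expect_false(any(plate$detected[absent]))
  dplate <- simulateDdpcr(truthDdpcr, smallDdpcrDesign(seed = 8L), codAssay)
  dabsent <- grepl("^(ABS|NTC)", dplate$sample_id)
  expect_true(all(dplate$positive_droplets[dabsent] == 0L))
})

test_that("simulation is deterministic in the seed and sensitive to it", {
  a <- simulateQpcr(truthQpcr, smallQpcrDesign(seed = 10L), codAssay)
  b <- simulateQpcr(truthQpcr, smallQpcrDesign(seed = 10L), codAssay)
  c <- simulateQpcr(truthQpcr, smallQpcrDesign(seed = 11L), codAssay)
  expect_identical(a, b)
  expect_false(identical(a$ct, c$ct))
  da <- simulateDdpcr(truthDdpcr, smallDdpcrDesign(seed = 10L), codAssay)
  db <- simulateDdpcr(truthDdpcr, smallDdpcrDesign(seed = 10L), codAssay)
  dc <- simulateDdpcr(truthDdpcr, smallDdpcrDesign(seed = 12L), codAssay)
  expect_identical(da, db)
  expect_false(identical(da$positive_droplets, dc$positive_droplets))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulateQpcr(truthQpcr, smallQpcrDesign(seed = 3L), codAssay))
  expect_identical(runif(1), before)
})

test_that("non-finite generator parameters are rejected", {
  bad <- truthQpcr
  bad@beta0 <- NaN
  expect_error(simulateQpcr(bad, smallQpcrDesign(), codAssay), "finite")
  badd <- truthDdpcr
  badd@kappa0 <- Inf
  expect_error(simulateDdpcr(badd, smallDdpcrDesign(), codAssay), "finite")
})
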