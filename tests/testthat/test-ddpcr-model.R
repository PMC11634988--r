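test_that("cloglog and its inverse are exact and mutually inverse", {
  expect_equal(cloglog(1 - exp(-1)), 0)
  expect_equal(cloglog(0.5), log(log(2)))
  for (p in c(1e-6, 0.5, 1 - 1e-6))
    expect_equal(invCloglog(cloglog(p)), p, tolerance = 1e-12)
  expect_error(cloglog(0), "strictly inside")
  expect_error(cloglog(1), "strictly inside")
  # linearity on the generator curve: cloglog(omega) is linear in log10 C
  k <- truthDdpcr
  grid <- seq(-3, 4, by = 0.5)
  eta <- cloglog(invCloglog(k@kappa0 + k@kappa1 * grid))
  slopes <- diff(eta) / diff(grid)
  expect_equal(slopes, rep(k@kappa1, length(slopes)), tolerance = 1e-9)
})

test_that("the Poisson single-well formula behaves at its boundaries", {
  expect_equal(poissonEstimate(0, 20000, 0.00085), 0)
  w <- round((1 - exp(-0.85)) * 1e6)
  expect_equal(poissonEstimate(w, 1e6, 0.00085), 1000, tolerance = 1e-4)
  expect_error(poissonEstimate(100, 100, 0.00085), "saturated")
})

test_that("the binomial log-likelihood is additive over replicates", {
  k <- DdpcrParams(cloglog(0.5), log(10))  # omega = 0.5 at c = 0
  one <- data.frame(assay_id = "cod", sample_id = "U1",
                    sample_type = "unknown", nominal_conc = NA_real_,
                    replicate = 1L, positive_droplets = 1L,
                    total_droplets = 2L)
  expect_equal(ddpcrLogLikelihood(k, c(U1 = 0), one), log(0.5))
  two <- rbind(one, one)
  expect_equal(ddpcrLogLikelihood(k, c(U1 = 0), two), 2 * log(0.5))
  # 5-replicate oracle: brute-force per-replicate binomial sum
  set.seed(21)
  reps <- data.frame(assay_id = "cod", sample_id = "U1",
                     sample_type = "unknown", nominal_conc = NA_real_,
                     replicate = 1:5,
                     positive_droplets = rbinom(5, 2000, 0.3),
                     total_droplets = 2000L)
  lat <- c(U1 = -0.7)
  om <- 1 - exp(-exp(truthDdpcr@kappa0 + truthDdpcr@kappa1 * lat[["U1"]]))
  oracle <- sum(vapply(1:5, function(i)
    dbinom(reps$positive_droplets[i], reps$total_droplets[i], om,
           log = TRUE), numeric(1)))
  expect_equal(ddpcrLogLikelihood(truthDdpcr, lat, reps), oracle)
  expect_error(ddpcrLogLikelihood(truthDdpcr, c(OTHER = 0), reps), "U1")
})

test_that("kappa diagnostics invert the calibration identities", {
  expect_equal(dropletVolumeFromIntercept(0), 1)
  expect_equal(efficiencyFromSlope(log(10)), 1)
  expect_equal(efficiencyFromSlope(2.3), 2.3 / log(10))
  expect_equal(efficiencyFromSlope(1.1513), 0.5, tolerance = 1e-4)
  expect_equal(dropletVolumeFromIntercept(log(0.00085)), 0.00085)
})

test_that("fitDdpcr estimates concentrations and is seed-reproducible", {
  plate <- simulateDdpcr(truthDdpcr,
                         smallDdpcrDesign(seed = 3L, nUnknown = 6L),
                         codAssay)
  fit <- fitDdpcr(plate, config = quickConfig(seed = 4L))
  est <- estimates(fit)
  truth <- attr(plate, "truth")
  unk <- grepl("^UNK", est$sample_id)
  tru <- truth$true_log10[match(est$sample_id[unk], truth$sample_id)]
  hits <- sum(est$ci_low[unk] <= tru & tru <= est$ci_high[unk])
  expect_gte(hits, sum(unk) - 1L)
  fit2 <- fitDdpcr(plate, config = quickConfig(seed = 4L))
  expect_identical(posteriorDraws(fit), posteriorDraws(fit2))
  # a sample with zero droplets everywhere is a non-detect
  absent <- grepl("^ABS", est$sample_id)
  expect_true(all(10^est$log10_c_median[absent] < 1e-3))
  expect_false(any(est$is_detect[absent]))
})

test_that("replicate aggregation never widens the credible interval", {
  # with the calibration line fixed, pooling n replicates of the same
  # sample must not lose information relative to any single replicate
  set.seed(31)
  wells <- data.frame(assay_id = "cod", sample_id = "U1",
                      sample_type = "unknown", nominal_conc = NA_real_,
                      replicate = 1:4,
                      positive_droplets = rbinom(4, 20000, 0.005),
                      total_droplets = 20000L)
  pooled <- fitDdpcr(wells, config = quickConfig(seed = 7L, nIter = 2000L),
                     fixedParams = truthDdpcr)
  wPooled <- estimates(pooled)$ci_width
  for (i in 1:4) {
    single <- fitDdpcr(wells[i, ],
                       config = quickConfig(seed = 7L, nIter = 2000L),
                       fixedParams = truthDdpcr)
    expect_lte(wPooled, estimates(single)$ci_width * 1.05)
  }
})

test_that("saturated wells are dropped with a warning, bad standards error", {
  plate <- simulateDdpcr(truthDdpcr, smallDdpcrDesign(seed = 5L), codAssay)
  sat <- plate
  sat$positive_droplets[1] <- sat$total_droplets[1]
  expect_warning(fitDdpcr(sat, config = quickConfig(seed = 1L)), "saturated")
  zero <- plate
  zero$positive_droplets[zero$sample_type == "standard"] <- 0L
  expect_error(suppressWarnings(
    fitDdpcr(zero, config = quickConfig(seed = 1L))), "unidentifiable")
  oneStd <- plate[is.na(plate$nominal_conc) | plate$nominal_conc == 10, ]
  expect_error(fitDdpcr(oneStd, config = quickConfig(seed = 1L)),
               "2 distinct")
})
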