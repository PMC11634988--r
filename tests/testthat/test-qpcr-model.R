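test_that("detection probability and Ct moments follow the linear predictors", {
  p <- QpcrParams(0, 2, 38, -3.32, -1.2, -0.25)
  expect_equal(qpcrDetectionProb(p, 0), 0.5)
  expect_gt(qpcrDetectionProb(p, 50), 1 - 1e-12)
  p2 <- QpcrParams(1, 2, 38, -3.32, -1.2, -0.25)
  expect_equal(qpcrDetectionProb(p2, -0.5), 0.5)
  # monotone in concentration
  grid <- seq(-4, 6, by = 0.5)
  expect_true(all(diff(qpcrDetectionProb(p, grid)) > 0))

  m <- qpcrCtMoments(p, 3)
  expect_equal(m$mean_ct, 38 - 3.32 * 3)
  expect_equal(m$sd_ct, exp(-1.2 - 0.25 * 3))
  p3 <- QpcrParams(0, 2, 38, -3.32, -1.2, 0)
  expect_equal(qpcrCtMoments(p3, 7)$sd_ct, exp(-1.2))
  expect_equal(qpcrCtMoments(p2, -1)$sd_ct, exp(-0.95))
  # log-linearity of the sd: exact identity at any two points
  s <- qpcrCtMoments(p, c(0, 1, 2))$sd_ct
  expect_equal(log(s[3]) - log(s[2]), log(s[2]) - log(s[1]))
})

test_that("the joint log-likelihood decomposes into per-replicate terms", {
  p <- truthQpcr
  rec <- data.frame(
    assay_id = "cod",
    sample_id = c("S1", "S1", "U1", "U1", "U1"),
    sample_type = c("standard", "standard", "unknown", "unknown", "unknown"),
    nominal_conc = c(100, 100, NA, NA, NA),
    replicate = c(1L, 2L, 1L, 2L, 3L),
    ct = c(31.2, NA, 39.0, NA, 38.5))
  lat <- c(U1 = -0.4)
  # independent per-term oracle, written against the model definition
  term <- function(type, conc, ct) {
    cc <- if (type == "standard") log10(conc) else lat[["U1"]]
    th <- plogis(p@phi0 + p@phi1 * cc)
    if (is.na(ct)) return(log(1 - th))
    log(th) + dnorm(ct, p@beta0 + p@beta1 * cc,
                    exp(p@gamma0 + p@gamma1 * cc), log = TRUE)
  }
  oracle <- sum(mapply(term, rec$sample_type, rec$nominal_conc, rec$ct))
  expect_equal(qpcrLogLikelihood(p, lat, rec), oracle)
  # removing one replicate changes the total by exactly that term
  expect_equal(qpcrLogLikelihood(p, lat, rec[-3, ]),
               oracle - term("unknown", NA, 39.0))
  # single detected standard at its own mean: log(theta) - log(sd*sqrt(2pi))
  mu1 <- p@beta0 + p@beta1 * 2
  one <- rec[1, ]; one$ct <- mu1
  expect_equal(qpcrLogLikelihood(p, lat, one),
               log(plogis(p@phi0 + p@phi1 * 2)) -
                 log(exp(p@gamma0 + p@gamma1 * 2) * sqrt(2 * pi)))
  # unmatched sample is an error
  expect_error(qpcrLogLikelihood(p, c(OTHER = 1), rec), "U1")
})

test_that("fitQpcr recovers sensible posteriors and is seed-reproducible", {
  plate <- simulateQpcr(truthQpcr, smallQpcrDesign(seed = 2L, nUnknown = 6L),
                        codAssay)
  fit <- fitQpcr(plate, config = quickConfig(seed = 5L))
  expect_s4_class(fit, "PcrFit")
  est <- estimates(fit)
  truth <- attr(plate, "truth")
  # every simulated unknown's truth inside its central 95% interval would
  # be unusual to fail for all; require at least 5 of 7 (6 unknowns + ABS)
  unk <- grepl("^UNK", est$sample_id)
  tru <- truth$true_log10[match(est$sample_id[unk], truth$sample_id)]
  hits <- sum(est$ci_low[unk] <= tru & tru <= est$ci_high[unk])
  expect_gte(hits, sum(unk) - 1L)
  # deterministic given the seed
  fit2 <- fitQpcr(plate, config = quickConfig(seed = 5L))
  expect_identical(posteriorDraws(fit), posteriorDraws(fit2))
  fit3 <- fitQpcr(plate, config = quickConfig(seed = 6L))
  expect_false(identical(posteriorDraws(fit), posteriorDraws(fit3)))
  # negative controls excluded by default
  expect_false(any(grepl("^NTC", est$sample_id)))
  inc <- fitQpcr(plate, config = quickConfig(seed = 5L),
                 includeControls = TRUE)
  expect_true(any(grepl("^NTC", estimates(inc)$sample_id)))
})

test_that("an all-non-detect unknown is pushed far below the standards", {
  des <- updateDesign(defaultDesign("qpcr"), nUnknown = 4L,
                      nAbsentSamples = 2L, nNegativeControls = 0L, seed = 11L)
  plate <- simulateQpcr(truthQpcr, des, codAssay)
  fit <- fitQpcr(plate, config = quickConfig(seed = 2L))
  est <- estimates(fit)
  absent <- grepl("^ABS", est$sample_id)
  expect_true(any(absent))
  # posterior mass sits below the 50%-detection concentration and far
  # below the single-copy limit of one 20 uL reaction (0.05 copies/uL)
  expect_true(all(est$log10_c_median[absent] < log10(qpcrLowerLimit(20, 1))))
  expect_true(all(est$ci_low[absent] < -3))
})

test_that("continuous-only mode flags prior-driven samples", {
  des <- updateDesign(defaultDesign("qpcr"), nUnknown = 3L,
                      nAbsentSamples = 1L, nNegativeControls = 0L, seed = 12L)
  plate <- simulateQpcr(truthQpcr, des, codAssay)
  fit <- fitQpcr(plate, config = quickConfig(seed = 3L),
                 mode = "continuous_only")
  est <- estimates(fit)
  nd <- tapply(plate$detected[plate$sample_type == "unknown"],
               plate$sample_id[plate$sample_type == "unknown"], sum)
  allNd <- names(nd)[nd == 0]
  expect_true(length(allNd) > 0)
  expect_true(all(est$prior_driven[est$sample_id %in% allNd]))
  expect_false(any(est$prior_driven[!est$sample_id %in% allNd]))
  # prior-driven estimates reproduce the prior quantiles
  pr <- qpcrPriors()
  expect_equal(est$log10_c_median[est$sample_id == allNd[1]],
               pr$log10C$mu, tolerance = 0.2)
  expect_equal(est$ci_width[est$sample_id == allNd[1]],
               2 * qnorm(0.975) * pr$log10C$sd, tolerance = 0.5)
  # phi is not part of the continuous-only model
  expect_false(any(grepl("^phi", colnames(posteriorDraws(fit)))))
})

test_that("degenerate qPCR inputs are rejected", {
  plate <- simulateQpcr(truthQpcr, smallQpcrDesign(seed = 2L), codAssay)
  oneStd <- plate[plate$nominal_conc %in% c(NA, 100), ]
  expect_error(fitQpcr(oneStd, config = quickConfig()), "2 distinct")
  allNd <- plate
  allNd$ct[allNd$sample_type == "standard"] <- NA
  allNd$detected[allNd$sample_type == "standard"] <- FALSE
  expect_error(fitQpcr(allNd, config = quickConfig()), "non-detect")
})
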