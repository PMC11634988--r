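test_that("qPCR table parsing derives detection from the ct token", {
  csv <- paste(
    "assay_id,sample_id,sample_type,nominal_conc,replicate,ct",
    "cod,S1,standard,100,1,31.2",
    "cod,E7,unknown,,2,Undetermined",
    "cod,E8,unknown,,1,NA",
    "cod,E9,unknown,,1,",
    "cod,N1,negative_control,,1,Undetermined",
    sep = "\n")
  rec <- readQpcrTable(textConnection(csv), codAssay)
  expect_equal(nrow(rec), 5L)
  expect_equal(rec$ct[1], 31.2)
  expect_true(rec$detected[1])
  expect_equal(rec$nominal_conc[1], 100)
  expect_false(any(rec$detected[2:5]))
  expect_true(all(is.na(rec$ct[2:5])))
})

test_that("qPCR table validation rejects malformed rows", {
  head <- "assay_id,sample_id,sample_type,nominal_conc,replicate,ct"
  expect_error(
    readQpcrTable(textConnection(paste(
      head, "cod,S1,standard,,1,31.2", sep = "\n")), codAssay),
    "standard row")
  expect_error(
    readQpcrTable(textConnection(paste(
      head, "cod,S1,standard,100,1,46.5", sep = "\n")), codAssay),
    "maxCycles")
  expect_error(
    readQpcrTable(textConnection(paste(
      head, "herring,S1,standard,100,1,31.2", sep = "\n")), codAssay),
    "registry")
  expect_error(
    readQpcrTable(textConnection(paste(
      "assay_id,sample_id,sample_type,nominal_conc,replicate",
      "cod,S1,standard,100,1", sep = "\n")), codAssay),
    "ct")
})

test_that("ddPCR table parsing enforces droplet-count invariants", {
  csv <- paste(
    "assay_id,sample_id,sample_type,nominal_conc,replicate,positive_droplets,total_droplets",
    "cod,S3,standard,10,1,169,18650",
    "cod,E2,unknown,,3,0,20112",
    sep = "\n")
  rec <- readDdpcrTable(textConnection(csv), codAssay)
  expect_equal(rec$positive_droplets, c(169L, 0L))
  expect_equal(rec$total_droplets, c(18650L, 20112L))
  head <- "assay_id,sample_id,sample_type,nominal_conc,replicate,positive_droplets,total_droplets"
  expect_error(
    readDdpcrTable(textConnection(paste(
      head, "cod,E2,unknown,,3,21000,20000", sep = "\n")), codAssay),
    "0 <= W <= U")
  expect_error(
    readDdpcrTable(textConnection(paste(
      head, "cod,E2,unknown,,3,0,0", sep = "\n")), codAssay),
    "positive")
})

test_that("plate write/read round-trip is the identity on both record types", {
  plate <- simulateQpcr(truthQpcr, smallQpcrDesign(seed = 4L), codAssay)
  path <- tempfile(fileext = ".csv")
  writePlateTable(plate, path)
  back <- readQpcrTable(path, codAssay)
  expect_equal(back$sample_id, plate$sample_id)
  expect_equal(back$ct, plate$ct, tolerance = 1e-12)
  expect_equal(back$detected, plate$detected)
  expect_equal(back$nominal_conc, plate$nominal_conc)

  dplate <- simulateDdpcr(truthDdpcr, smallDdpcrDesign(seed = 4L), codAssay)
  writePlateTable(dplate, path)
  dback <- readDdpcrTable(path, codAssay)
  expect_equal(dback$positive_droplets, dplate$positive_droplets)
  expect_equal(dback$total_droplets, dplate$total_droplets)
})

test_that("estimate tables round-trip to at least 6 decimals", {
  set.seed(9)
  n <- 50L
  med <- rnorm(n)
  lo <- med - abs(rnorm(n))
  hi <- med + abs(rnorm(n))
  est <- data.frame(
    sample_id = sprintf("E%02d", seq_len(n)), assay_id = "cod",
    method = "ddpcr", log10_c_median = med, log10_c_mean = med + 0.01,
    ci_low = lo, ci_high = hi, ci_width = hi - lo,
    is_detect = med > -3)
  path <- tempfile(fileext = ".csv")
  writeEstimates(est, path)
  back <- readEstimates(path)
  expect_equal(names(back),
               c("sample_id", "assay_id", "method", "log10_c_median",
                 "log10_c_mean", "ci_low", "ci_high", "ci_width",
                 "is_detect"))
  for (col in c("log10_c_median", "log10_c_mean", "ci_low", "ci_high",
                "ci_width"))
    expect_equal(back[[col]], est[[col]], tolerance = 1e-7)
  expect_identical(back$is_detect, est$is_detect)

  dup <- rbind(est, est[1, ])
  expect_error(writeEstimates(dup, path), "duplicate")
  expect_error(writeEstimates(est[0, ], path), "non-empty")
})

test_that("domain-type validity catches invariant violations", {
  expect_error(QpcrParams(0, -1, 38, -3.3, 0, 0), "phi1")
  expect_error(QpcrParams(0, 1, 38, 3.3, 0, 0), "beta1")
  expect_error(DdpcrParams(0, -2), "kappa1")
  expect_error(PcrAssay("cod", reactionVolumeUl = -1), "reactionVolumeUl")
  expect_error(PcrAssay("cod", dropletVolumeUl = 0), "dropletVolumeUl")
  expect_silent(validObject(defaultQpcrParams()))
})
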