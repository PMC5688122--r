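test_that("embryonic-division model halves the expected MAF per division", {
  expect_identical(embryonicMaf(1), 0.25)
  expect_identical(embryonicMaf(2), 0.125)
  d <- 1:10
  expect_equal(embryonicMaf(d + 1), embryonicMaf(d) / 2)
  expect_error(embryonicMaf(0), ">= 1")
  expect_error(embryonicMaf(1.5), "whole number")
})

test_that("noise-free families put the base MAF in every tissue", {
  cfg <- generatorConfig(nFamilies = 5, mosaicFamilyFraction = 1,
                         paternalFraction = 1, spermElevation = 1,
                         tissueNoiseSd = 0, seed = 1L)
  cohort <- simulateCohort(cfg)
  fam <- families(cohort)
  smp <- samples(cohort)
  for (i in seq_len(nrow(fam))) {
    rows <- smp[smp$family_id == fam$family_id[i] & smp$person == "father", ]
    expect_equal(rows$maf, rep(fam$true_base_maf[i], nrow(rows)))
  }
  # probands are constitutional heterozygotes
  expect_true(all(smp$maf[smp$person == "proband"] == 0.5))
  # base MAFs come from the embryonic-division model
  expect_equal(fam$true_base_maf, embryonicMaf(fam$true_division))
})

test_that("fixed seeds make cohorts and droplet runs fully reproducible", {
  cfg <- generatorConfig(nFamilies = 12, seed = 99L)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(samples(c1), samples(c2))
  expect_identical(families(c1), families(c2))
  set.seed(5); r1 <- simulateDropletRun(0.01, cfg)
  set.seed(5); r2 <- simulateDropletRun(0.01, cfg)
  expect_identical(r1@nMutant, r2@nMutant)
  expect_identical(r1@nEmpty, r2@nEmpty)
})

test_that("division weights shape the MAF distribution as designed", {
  cfg <- generatorConfig(nFamilies = 2000, mosaicFamilyFraction = 1,
                         divisionWeights = c("1" = 0.5, "2" = 0.5),
                         tissueNoiseSd = 0, spermElevation = 1, seed = 17L)
  cohort <- simulateCohort(cfg)
  base <- families(cohort)$true_base_maf
  expect_setequal(unique(base), c(0.25, 0.125))
  expect_equal(mean(base == 0.25), 0.5, tolerance = 3 * sqrt(0.25 / 2000))
})

test_that("droplet-run generator recovers the loading model", {
  cfg <- generatorConfig(nTemplates = 1e6, nDroplets = 1e7)
  set.seed(31)
  expect_equal(simulateDropletRun(0, cfg)@nMutant, 0)

  # parameter recovery at 1e6 templates: |bias| < 3 binomial SEs
  run <- simulateDropletRun(0.5, cfg)
  est <- estimateMaf(run)
  expect_lt(abs(est@maf - 0.5), 3 * sqrt(0.25 / 1e6))

  # total template recovery through the occupancy relation
  lam <- poissonLambda(dropletTotal(run) - run@nEmpty, dropletTotal(run))
  expect_equal(lam * cfg@nDroplets, 1e6, tolerance = 0.01)

  # crowding: more templates than droplets boosts double positives
  sparse <- simulateDropletRun(0.5, generatorConfig(nTemplates = 1e5,
                                                    nDroplets = 1e6))
  crowded <- simulateDropletRun(0.5, generatorConfig(nTemplates = 3e6,
                                                     nDroplets = 1e6))
  fracDouble <- function(x) x@nDouble / dropletTotal(x)
  expect_gt(fracDouble(crowded), 10 * fracDouble(sparse))
})

test_that("dilution series follows the stock over the dilution ladder", {
  expect_equal(simulateDilutionSeries(),
               c(0.05, 0.005, 5e-4, 5e-5, 5e-6, 5e-7))
  expect_equal(simulateDilutionSeries(nSteps = 0), numeric(0))
  expect_equal(simulateDilutionSeries(dilutionFactor = 2, nSteps = 2),
               c(0.25, 0.125))
  expect_error(simulateDilutionSeries(stockMaf = 0), "stockMaf")
  expect_error(simulateDilutionSeries(dilutionFactor = -1), "positive")
})

test_that("detection power respects platform models and monotonicity", {
  cfg <- generatorConfig()
  expect_equal(detectionPower("Sanger", 0.06, cfg, nReps = 5)$power, 1)
  expect_equal(detectionPower("Sanger", 0.04, cfg, nReps = 5)$power, 0)
  expect_error(detectionPower("ddSeq", 0.1, cfg), "unknown platform")

  # nothing is ever detected at MAF zero (no false-positive model)
  set.seed(23)
  expect_equal(detectionPower("PASM", 0, cfg, nReps = 100)$power, 0)
  expect_equal(detectionPower("mDDPCR", 0, cfg, nReps = 20)$power, 0)

  # power is monotone non-decreasing in the true MAF
  p <- vapply(c(1e-4, 1e-3, 1e-2), function(m)
    detectionPower("PASM", m, cfg, nReps = 200)$power, numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("elevated sperm MAFs are detected by the transmission pipeline", {
  # power property: with a true 1.5-fold germline elevation and 10 mosaic
  # fathers, the transmission-conditioned probability is < 0.05 in the
  # large majority of replicate cohorts
  cfg <- generatorConfig(nFamilies = 10, mosaicFamilyFraction = 1,
                         paternalFraction = 1, spermElevation = 1.5)
  set.seed(77)
  hits <- vapply(1:60, function(i) {
    cohort <- simulateCohort(cfg)
    correctedTransmissionP(transmissionPairs(cohort)) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("a generated cohort feeds the whole pipeline unchanged", {
  cfg <- generatorConfig(nFamilies = 400, seed = 123L)
  cohort <- simulateCohort(cfg)
  fam <- families(cohort)
  # recover the mosaic-family fraction from the emitted records
  mosaicFrac <- mean(fam$parental_origin != "none")
  expect_lt(abs(mosaicFrac - cfg@mosaicFamilyFraction),
            3 * sqrt(0.26 * 0.74 / 400))
  # sperm elevation sign: sperm exceeds blood in most mosaic fathers
  pairs <- transmissionPairs(cohort)
  expect_gt(nrow(pairs), 30)
  expect_gt(median(pairs$maf_sperm - pairs$maf_blood), 0)
  # round trip through the cohort file dialect
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCohort(cohort, f)
  expect_equal(nrow(families(readCohort(f))), 400L)
})
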