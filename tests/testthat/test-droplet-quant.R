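test_that("Poisson occupancy inverts the positive-droplet fraction", {
  expect_equal(poissonLambda(0, 10000), 0)
  expect_equal(poissonLambda(6321, 10000), 1, tolerance = 1e-3)
  expect_error(poissonLambda(10000, 10000), "saturated")
  expect_error(poissonLambda(-1, 100), "0 <= nPositive")
  expect_error(poissonLambda(5, 0), "positive")
})

test_that("Clopper-Pearson matches binom.test and handles the boundaries", {
  # independent oracle: the CI reported by stats::binom.test
  for (n in c(10L, 100L, 10000L)) {
    for (k in unique(c(0L, 1L, 5L, n %/% 2L, n))) {
      ours <- clopperPearson(k, n)
      ref <- stats::binom.test(k, n)$conf.int
      expect_equal(unname(ours[1L, ]), as.vector(ref), tolerance = 1e-10)
    }
  }
  expect_equal(unname(clopperPearson(0, 100)[1L, "upper"]),
               1 - 0.025^(1 / 100), tolerance = 1e-10)
  expect_identical(unname(clopperPearson(0, 100)[1L, "lower"]), 0)
  expect_identical(unname(clopperPearson(100, 100)[1L, "upper"]), 1)
  expect_error(clopperPearson(5, 10, conf = 1.2), "conf")
  expect_error(clopperPearson(11, 10), "k <= n")
  # Wilson alternative stays inside [0,1] and brackets the MLE
  w <- clopperPearson(3, 10, method = "wilson")
  expect_true(w[1L, "lower"] < 0.3 && w[1L, "upper"] > 0.3)
})

test_that("MAF estimation from droplet counts matches the binomial oracle", {
  est <- estimateMaf(DropletCounts(0, 5000))
  expect_equal(est@maf, 0)
  expect_equal(est@ciLow, 0)

  est <- estimateMaf(DropletCounts(50, 50))
  expect_equal(est@maf, 0.5)
  expect_equal(est@ciLow, qbeta(0.025, 50, 51), tolerance = 1e-10)
  expect_equal(est@ciHigh, qbeta(0.975, 51, 50), tolerance = 1e-10)

  est <- estimateMaf(DropletCounts(5, 9995))
  expect_equal(est@maf, 5e-4)
  expect_equal(est@ciLow, qbeta(0.025, 5, 9996), tolerance = 1e-12)
  # chi-square (Poisson-limit) representation of the rare-event lower bound
  expect_equal(est@ciLow, qchisq(0.025, 10) / 2 / 10000, tolerance = 1e-3)

  # double-positive droplets contribute one molecule proxy to each channel
  est <- estimateMaf(DropletCounts(10, 10, nDouble = 5))
  expect_equal(est@maf, 15 / 30)

  expect_error(estimateMaf(DropletCounts(0, 0, 0, 1000)), "no informative")
  expect_error(DropletCounts(-1, 10), "non-negative")
})

test_that("lambda-corrected and raw estimates agree at low occupancy", {
  set.seed(42)
  cfg <- generatorConfig(nTemplates = 2e5, nDroplets = 1e7)  # occupancy 2%
  for (maf in c(0.01, 0.1, 0.5)) {
    counts <- simulateDropletRun(maf, cfg)
    raw <- estimateMaf(counts)@maf
    lam <- estimateMaf(counts, lambdaCorrect = TRUE)@maf
    expect_equal(lam, raw, tolerance = 0.01)
  }
})

test_that("homology correction rescales point and bounds, monotone, clamped", {
  expect_equal(correctHomology(0.0145, 3), 0.0435)
  expect_equal(correctHomology(0.1111, 4), 0.4444)
  x <- runif(20)
  expect_equal(correctHomology(x, 1L), x)
  expect_equal(correctHomology(0.6, 2), 1)  # clamps at 1
  # monotone in the raw MAF
  xs <- sort(runif(50))
  expect_true(all(diff(correctHomology(xs, 3)) >= 0))

  est <- estimateMaf(DropletCounts(5, 9995))
  est <- correctHomology(est, 3L)
  expect_equal(est@mafCorrected, 3 * est@maf)
  expect_true(est@ciLowCorrected <= est@mafCorrected)
  expect_true(est@mafCorrected <= est@ciHighCorrected)
  expect_error(correctHomology(0.1, 0), ">= 1")
})

test_that("calling rule separates heterozygotes, mosaics and negatives", {
  assay <- AssayConfig()
  mk <- function(maf, lo, hi) new("MafEstimate", maf = maf, ciLow = lo,
                                  ciHigh = hi, kEff = 0, nEff = 1)
  expect_equal(callSample(mk(0.4963, 0.49, 0.50), assay, "proband")@call,
               "heterozygous_band")
  est <- callSample(mk(0.3298, 0.32, 0.34), assay, "proband")
  expect_equal(est@call, "mosaic")
  expect_true(est@putativeMosaicProband)
  expect_equal(callSample(mk(5e-5, 0, 2e-4), assay)@call, "not_detected")
  expect_equal(callSample(mk(0.01, 5e-4, 0.02), assay)@call, "mosaic")
  # corrected values are what gets thresholded
  raw <- correctHomology(mk(0.001, 4e-5, 0.002), 3L)
  expect_equal(callSample(raw, AssayConfig(homologyCopies = 3))@call, "mosaic")
  expect_error(callSample(mk(0.1, 0.05, 0.2),
                          AssayConfig(homologyCopies = 2)),
               "correctHomology")
})

test_that("raising the detection threshold never creates new mosaic calls", {
  set.seed(7)
  for (i in 1:25) {
    k <- rpois(1, 5)
    est <- estimateMaf(DropletCounts(k, 50000 - k))
    thresholds <- sort(runif(5, 1e-5, 0.01))
    calls <- vapply(thresholds, function(th)
      callSample(est, AssayConfig(detectThreshold = th))@call, character(1))
    mosaic <- calls == "mosaic"
    # once lost, a mosaic call never reappears at a higher threshold
    expect_true(all(diff(mosaic) <= 0))
  }
})

test_that("negative-control calibration floors the threshold at 1e-4", {
  expect_equal(calibrateThreshold(list()), 1e-4)
  lo <- estimateMaf(DropletCounts(0, 50000))
  expect_equal(calibrateThreshold(list(lo)), 1e-4)
  hi <- estimateMaf(DropletCounts(30, 50000))
  expect_equal(calibrateThreshold(list(lo, hi)), hi@ciHigh)
})

test_that("droplet TSV quantification applies correction and calling", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tn_mutant\tn_wildtype\tn_double\tn_empty",
               "pos\t500\t500\t0\t9000",
               "neg\t0\t1000\t0\t9000"), f)
  out <- quantifyDroplets(f, AssayConfig())
  expect_equal(out$call, c("heterozygous_band", "not_detected"))
  expect_equal(out$maf[1L], 0.5)
  expect_equal(attr(out, "detectThreshold"), 1e-4)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tcount", "x\t1"), bad)
  expect_error(quantifyDroplets(bad), "columns")
})
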