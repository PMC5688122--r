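#' Construct droplet counts
#'
#' @param nMutant,nWildtype,nDouble,nEmpty non-negative whole numbers of
#'   droplets gated as mutant-only positive, wild-type-only positive,
#'   double positive and empty.
#' @return A [DropletCounts-class] object.
#' @examples
#' DropletCounts(nMutant = 5, nWildtype = 9995, nDouble = 0, nEmpty = 90000)
#' @export
DropletCounts <- function(nMutant, nWildtype, nDouble = 0, nEmpty = 0) {
  new("DropletCounts", nMutant = as.numeric(nMutant),
      nWildtype = as.numeric(nWildtype), nDouble = as.numeric(nDouble),
      nEmpty = as.numeric(nEmpty))
}

#' Total droplets in a run
#'
#' @param counts a [DropletCounts-class] object.
#' @return Sum of the four droplet classes.
#' @export
dropletTotal <- function(counts) {
  stopifnot(is(counts, "DropletCounts"))
  counts@nMutant + counts@nWildtype + counts@nDouble + counts@nEmpty
}

#' Mean templates per droplet from Poisson occupancy
#'
#' Inverts the digital-PCR occupancy relation: if templates load into
#' droplets independently, the fraction of positive droplets is
#' `1 - exp(-lambda)`, so `lambda = -log(1 - nPositive/nTotal)`.
#'
#' @param nPositive number of positive droplets (for one channel).
#' @param nTotal total number of droplets; must be positive.
#' @return Mean template molecules per droplet (non-negative).
#' @examples
#' poissonLambda(6321, 10000)  # ~1 template per droplet
#' @export
poissonLambda <- function(nPositive, nTotal) {
  stopifnot(length(nPositive) == length(nTotal) || length(nTotal) == 1L)
  if (any(nTotal <= 0)) stop("'nTotal' must be positive")
  if (any(nPositive < 0) || any(nPositive > nTotal))
    stop("need 0 <= nPositive <= nTotal")
  if (any(nPositive == nTotal))
    stop("all droplets positive: occupancy is saturated and undefined")
  -log1p(-nPositive / nTotal)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Central exact interval for a binomial proportion from the beta quantile
#' representation: lower bound `qbeta(a/2, k, n-k+1)` (0 when `k = 0`),
#' upper bound `qbeta(1-a/2, k+1, n-k)` (1 when `k = n`). This is the
#' interval family used for all droplet-count MAF estimates: exactness
#' matters at the mutant-droplet counts (k <= 5) where mosaic calls are
#' decided.
#'
#' @param k number of successes (vectorised).
#' @param n number of trials.
#' @param conf confidence level in (0, 1); default 0.95.
#' @param method `"clopper-pearson"` (default) or `"wilson"` for the Wilson
#'   score interval.
#' @return A two-column matrix with columns `lower` and `upper`.
#' @examples
#' clopperPearson(5, 10000)
#' @export
clopperPearson <- function(k, n, conf = 0.95,
                           method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (length(conf) != 1L || is.na(conf) || conf <= 0 || conf >= 1)
    stop("'conf' must be a single value in (0, 1)")
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n")
  a <- 1 - conf
  if (method == "clopper-pearson") {
    lower <- ifelse(k == 0, 0, stats::qbeta(a / 2, k, n - k + 1))
    upper <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 1, n - k))
  } else {
    z <- stats::qnorm(1 - a / 2)
    p <- k / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lower <- pmax(0, ctr - hw)
    upper <- pmin(1, ctr + hw)
  }
  cbind(lower = lower, upper = upper)
}

#' Maximum-likelihood MAF estimate from droplet counts
#'
#' Point estimate and exact 95% binomial confidence interval of the mutant
#' allelic fraction measured by one droplet run.
#'
#' With `lambdaCorrect = FALSE` (default) each double-positive droplet
#' contributes one molecule proxy to each channel, giving
#' `maf = (nMutant + nDouble) / (nMutant + nWildtype + 2 nDouble)`. With
#' `lambdaCorrect = TRUE` the per-channel Poisson occupancies
#' `lambda = -log(1 - positive fraction)` replace the raw droplet counts,
#' which removes the bias from multiply-occupied droplets at high template
#' load; the confidence interval is then computed on the effective
#' (rounded) molecule counts. The two estimates agree closely whenever
#' occupancy is low (< ~5% positive droplets).
#'
#' @param counts a [DropletCounts-class] object.
#' @param lambdaCorrect logical; use Poisson channel occupancies.
#' @param conf confidence level, default 0.95.
#' @return A [MafEstimate-class] with the call slot unset.
#' @examples
#' estimateMaf(DropletCounts(5, 9995, 0, 90000))
#' @export
setMethod("estimateMaf", "DropletCounts",
  function(counts, lambdaCorrect = FALSE, conf = 0.95) {
    informative <- counts@nMutant + counts@nWildtype + counts@nDouble
    if (informative == 0)
      stop("no informative (positive) droplets: MAF is undefined")
    if (lambdaCorrect) {
      total <- dropletTotal(counts)
      lmu <- poissonLambda(counts@nMutant + counts@nDouble, total)
      lwt <- poissonLambda(counts@nWildtype + counts@nDouble, total)
      if (lmu + lwt == 0)
        stop("no informative (positive) droplets: MAF is undefined")
      maf <- lmu / (lmu + lwt)
      k <- round(lmu * total)
      n <- round((lmu + lwt) * total)
    } else {
      k <- counts@nMutant + counts@nDouble
      n <- counts@nMutant + counts@nWildtype + 2 * counts@nDouble
      maf <- k / n
    }
    ci <- clopperPearson(k, n, conf = conf)
    new("MafEstimate", maf = unname(maf), ciLow = unname(ci[1L, "lower"]),
        ciHigh = unname(ci[1L, "upper"]), kEff = unname(k), nEff = unname(n))
  })

#' Correct a MAF for co-amplified homologous regions
#'
#' When the digital-PCR target region matches `homologyCopies` near-identical
#' genomic regions (including the target itself), wild-type signal is drawn
#' from all copies while mutant signal comes only from the target, deflating
#' the raw MAF by the copy count. The correction multiplies the raw value by
#' `homologyCopies` and clamps at 1; applied to a [MafEstimate-class] it
#' rescales the point estimate and both interval bounds identically.
#'
#' @param x a fraction in [0, 1] (vectorised) or a [MafEstimate-class].
#' @param homologyCopies integer >= 1.
#' @return Same shape as `x`, corrected.
#' @examples
#' correctHomology(0.0145, 3)  # 0.0435
#' @export
setMethod("correctHomology", "numeric", function(x, homologyCopies) {
  homologyCopies <- as.integer(homologyCopies)
  if (is.na(homologyCopies) || homologyCopies < 1L)
    stop("'homologyCopies' must be an integer >= 1")
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("MAFs must lie in [0, 1]")
  pmin(1, x * homologyCopies)
})

#' @rdname correctHomology
#' @export
setMethod("correctHomology", "MafEstimate", function(x, homologyCopies) {
  homologyCopies <- as.integer(homologyCopies)
  if (is.na(homologyCopies) || homologyCopies < 1L)
    stop("'homologyCopies' must be an integer >= 1")
  x@homologyCopies <- homologyCopies
  x@mafCorrected <- correctHomology(x@maf, homologyCopies)
  x@ciLowCorrected <- correctHomology(x@ciLow, homologyCopies)
  x@ciHighCorrected <- correctHomology(x@ciHigh, homologyCopies)
  validObject(x)
  x
})

## corrected values when available, raw otherwise
correctedTriple <- function(estimate) {
  if (!is.na(estimate@mafCorrected))
    c(estimate@ciLowCorrected, estimate@mafCorrected, estimate@ciHighCorrected)
  else
    c(estimate@ciLow, estimate@maf, estimate@ciHigh)
}

#' Call the mosaic status of one sample
#'
#' Applies the calling rule to a (homology-corrected) MAF estimate:
#' `mosaic` when the 95% CI lower bound of the corrected MAF is at or above
#' the detection threshold (default `1e-4`) and the point estimate is below
#' the heterozygous band; `heterozygous_band` when the corrected point
#' estimate falls inside the band (default 40-60%), the pattern expected of a
#' constitutional heterozygote; `not_detected` otherwise. A proband whose
#' corrected MAF is positive but below the band is additionally flagged as a
#' putative mosaic proband.
#'
#' The threshold comparison is inclusive (`>=`).
#'
#' @param estimate a [MafEstimate-class]; homology correction must already
#'   have been applied when `assay@homologyCopies > 1`.
#' @param assay an [AssayConfig-class].
#' @param personRole `"proband"` or any other role label; only probands can
#'   be flagged putative mosaic.
#' @return The estimate with its `call` slot set.
#' @examples
#' est <- estimateMaf(DropletCounts(50, 50))
#' callSample(est, AssayConfig())
#' @export
setMethod("callSample", "MafEstimate",
  function(estimate, assay, personRole = "parent") {
    stopifnot(is(assay, "AssayConfig"))
    if (assay@homologyCopies > 1L && is.na(estimate@mafCorrected))
      stop("assay requires homology correction: apply correctHomology() first")
    tri <- correctedTriple(estimate)
    band <- assay@hetBand
    call <- if (tri[2L] >= band[1L] && tri[2L] <= band[2L]) {
      "heterozygous_band"
    } else if (tri[1L] >= assay@detectThreshold && tri[2L] < band[1L]) {
      "mosaic"
    } else {
      "not_detected"
    }
    estimate@call <- call
    estimate@putativeMosaicProband <-
      identical(personRole, "proband") && call == "mosaic"
    estimate
  })

#' Calibrate the detection threshold from negative controls
#'
#' Sets the mosaic-calling threshold to the largest 95% CI upper bound
#' observed across negative-control runs, floored at `1e-4`. Negative
#' controls bound the assay's background (probe cross-reactivity, gating
#' bleed-through); a sample is then only called when its CI lower bound
#' clears everything the controls can produce.
#'
#' @param controls a list of [MafEstimate-class] objects from
#'   negative-control runs.
#' @param floor minimum returned threshold, default `1e-4`.
#' @return A fraction usable as `detectThreshold` in [AssayConfig()].
#' @export
calibrateThreshold <- function(controls, floor = 1e-4) {
  if (!length(controls)) return(floor)
  stopifnot(all(vapply(controls, is, logical(1L), class2 = "MafEstimate")))
  upper <- vapply(controls, function(e) correctedTriple(e)[3L], numeric(1L))
  max(floor, max(upper))
}

#' Construct an assay configuration
#'
#' @param variant optional [VariantInfo-class].
#' @param homologyCopies,detectThreshold,hetBand see
#'   [AssayConfig-class].
#' @return An [AssayConfig-class] object.
#' @export
AssayConfig <- function(variant = NULL, homologyCopies = 1L,
                        detectThreshold = 1e-4, hetBand = c(0.40, 0.60)) {
  new("AssayConfig", variant = variant,
      homologyCopies = as.integer(homologyCopies),
      detectThreshold = detectThreshold, hetBand = hetBand)
}

#' Construct a variant identity
#'
#' @param chromosome,position,ref,alt,exon see [VariantInfo-class].
#' @return A [VariantInfo-class] object.
#' @export
VariantInfo <- function(chromosome, position, ref, alt, exon = NA_character_) {
  new("VariantInfo", chromosome = as.character(chromosome),
      position = as.integer(position), ref = ref, alt = alt, exon = exon)
}
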