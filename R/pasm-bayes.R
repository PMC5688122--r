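#' Posterior MAF from amplicon deep-sequencing counts
#'
#' Beta-binomial posterior for the mutant allelic fraction at an amplicon
#' site: with `k` mutant-supporting reads out of `depth` and a
#' `Beta(priorAlpha, priorBeta)` prior, the posterior is
#' `Beta(k + priorAlpha, depth - k + priorBeta)`. The point estimate is the
#' maximum a posteriori value: `k/depth` under the uniform prior (the
#' binomial MLE), otherwise the beta mode
#' `(priorAlpha + k - 1) / (priorAlpha + priorBeta + depth - 2)` when
#' defined. The credible interval is central and equal-tailed.
#'
#' This is a deliberate simplification of the full hierarchical
#' site-specific error model used by dedicated mosaic callers: the prior is
#' a single configurable beta distribution, with no sequencing-error
#' component beyond it.
#'
#' @param altCount mutant-supporting read count.
#' @param depth total reads at the site; must be >= 1.
#' @param priorAlpha,priorBeta positive beta prior parameters; default 1, 1
#'   (uniform).
#' @param conf credible level, default 0.95.
#' @return A [PosteriorMaf-class] object.
#' @examples
#' posteriorMaf(5, 1000)
#' @export
posteriorMaf <- function(altCount, depth, priorAlpha = 1, priorBeta = 1,
                         conf = 0.95) {
  if (priorAlpha <= 0 || priorBeta <= 0)
    stop("prior parameters must be positive")
  if (depth < 1) stop("'depth' must be >= 1")
  if (altCount < 0 || altCount > depth) stop("need 0 <= altCount <= depth")
  a <- altCount + priorAlpha
  b <- depth - altCount + priorBeta
  map <- if (priorAlpha == 1 && priorBeta == 1) {
    altCount / depth
  } else if (a > 1 && b > 1) {
    (a - 1) / (a + b - 2)
  } else {
    altCount / depth  # mode at a boundary or undefined: fall back to MLE
  }
  tail <- (1 - conf) / 2
  new("PosteriorMaf", map = map,
      criLow = min(map, stats::qbeta(tail, a, b)),
      criHigh = max(map, stats::qbeta(1 - tail, a, b)),
      priorAlpha = priorAlpha, priorBeta = priorBeta,
      altCount = as.numeric(altCount), depth = as.numeric(depth))
}

#' Concordance between two MAF-measuring platforms
#'
#' Ordinary least squares of one platform's MAFs on the other's, as used to
#' check that homology-corrected droplet-PCR MAFs agree with amplicon
#' sequencing estimates. Returns the slope, intercept, coefficient of
#' determination and the F-test p-value for the regression.
#'
#' @param mafA,mafB numeric vectors of paired MAFs (fractions or percent;
#'   the fit is scale-equivariant and R^2 is scale-invariant). Pairs with a
#'   missing value are dropped.
#' @return A list with `slope`, `intercept`, `rSquared`, `fPvalue`, `n` and
#'   the underlying `lm` fit.
#' @examples
#' platformConcordance(c(0, 0.5, 1), c(0.1, 0.4, 1.1))
#' @export
platformConcordance <- function(mafA, mafB) {
  stopifnot(length(mafA) == length(mafB))
  ok <- !is.na(mafA) & !is.na(mafB)
  mafA <- mafA[ok]; mafB <- mafB[ok]
  if (length(mafA) < 3L)
    stop("need at least 3 complete pairs")
  if (stats::var(mafA) == 0)
    stop("predictor platform has zero variance: fit is degenerate")
  fit <- stats::lm(mafB ~ mafA)
  sm <- summary(fit)
  f <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       rSquared = sm$r.squared,
       fPvalue = unname(stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE)),
       n = length(mafA), fit = fit)
}
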