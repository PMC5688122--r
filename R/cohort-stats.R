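#' Exact binomial test
#'
#' Exact test of `k` successes in `n` trials against success probability
#' `p0`. The two-sided p-value uses the minimum-likelihood rule: it sums the
#' probabilities of all outcomes no more probable than the observed one.
#' The doubling rule (twice the smaller tail, capped at 1) is available for
#' comparison.
#'
#' @param k,n counts with `0 <= k <= n`, `n >= 1`.
#' @param p0 null success probability in (0, 1).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param rule `"minlik"` (default) or `"double"`; only affects the
#'   two-sided p-value.
#' @return The p-value.
#' @examples
#' exactBinomialTest(18, 29)  # parent-of-origin sex bias, p = 0.26
#' @export
exactBinomialTest <- function(k, n, p0 = 0.5,
                              alternative = c("two.sided", "greater", "less"),
                              rule = c("minlik", "double")) {
  alternative <- match.arg(alternative)
  rule <- match.arg(rule)
  if (p0 <= 0 || p0 >= 1) stop("'p0' must lie in (0, 1)")
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n with n >= 1")
  if (alternative != "two.sided" || rule == "minlik")
    return(stats::binom.test(k, n, p = p0, alternative = alternative)$p.value)
  min(1, 2 * min(stats::pbinom(k, n, p0),
                 stats::pbinom(k - 1, n, p0, lower.tail = FALSE)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Hypergeometric exact test with the two-sided p-value from the
#' minimum-likelihood rule. Reports both the unconditional sample odds
#' ratio `ad/bc` (infinite when `bc = 0`) and the conditional
#' maximum-likelihood odds ratio from the noncentral hypergeometric
#' likelihood.
#'
#' @param table a 2x2 matrix of counts (rows = groups, columns = outcomes),
#'   or the count `a` with `b`, `c`, `d` given separately.
#' @param b,c,d optional scalar counts completing the table row-wise.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A list with `p.value`, `sampleOR` and `conditionalOR`.
#' @examples
#' fisherExact(8, 10, 4, 7)  # epileptic mosaic fathers vs mothers
#' @export
fisherExact <- function(table, b = NULL, c = NULL, d = NULL,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.null(b)) table <- matrix(c(table, b, c, d), 2L, 2L, byrow = TRUE)
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative")
  if (sum(table) == 0) stop("all-zero table is degenerate")
  ht <- stats::fisher.test(table, alternative = alternative)
  sampleOR <- if (table[1L, 2L] * table[2L, 1L] == 0) Inf else
    (table[1L, 1L] * table[2L, 2L]) / (table[1L, 2L] * table[2L, 1L])
  list(p.value = ht$p.value, sampleOR = sampleOR,
       conditionalOR = unname(ht$estimate))
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Two-sample rank test; exact enumeration of the rank-sum distribution
#' when `length(x) + length(y) <= 12` and there are no ties, otherwise the
#' normal approximation with tie correction and optional continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param continuity apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @return A list with `p.value`, `statistic` (W) and `exact`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6), alternative = "less")
#' @export
mannWhitneyU <- function(x, y,
                         alternative = c("two.sided", "greater", "less"),
                         continuity = TRUE) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = continuity))
  list(p.value = ht$p.value, statistic = unname(ht$statistic), exact = exact)
}

mosaicParentOf <- function(origin) {
  ifelse(origin == "paternal", "father",
         ifelse(origin == "maternal", "mother", NA_character_))
}

#' Summarise a mosaicism cohort
#'
#' Applies the cohort's descriptive counting rules to a validated
#' [CohortTable-class]:
#' \itemize{
#'   \item blood mosaic: family whose mosaic parent is flagged
#'     `blood_called`; sperm-only: `sperm_called` but not `blood_called`.
#'   \item Sanger-undetectable blood mosaics: blood-called families whose
#'     screening status is `undetectable`.
#'   \item peripheral tissue census: the mosaic parent's oral epithelium,
#'     saliva, hair follicle and urine samples (sperm and blood excluded);
#'     a sample is positive when its MAF is > 0.
#'   \item a father is "sperm highest" when his sperm MAF strictly exceeds
#'     every available non-blood peripheral tissue MAF (ties lose); the
#'     denominator is fathers with a sperm MAF and at least one other
#'     peripheral tissue.
#'   \item a mother is "blood highest" when her blood MAF strictly exceeds
#'     every available peripheral tissue MAF.
#'   \item MAF ranges are over called samples: sperm MAFs of sperm-called
#'     fathers, blood MAFs of blood-called mosaic parents. Father's-semen
#'     values in maternal-origin families are never counted.
#' }
#'
#' @param cohort a [CohortTable-class].
#' @return A [CohortSummary-class] object.
#' @examples
#' summarizeCohort(table1Fixture())
#' @export
setMethod("summarizeCohort", "CohortTable", function(cohort) {
  fam <- families(cohort)
  smp <- samples(cohort)
  mdd <- smp[smp$platform == "mDDPCR", , drop = FALSE]
  fam$mosaic_parent <- mosaicParentOf(fam$parental_origin)
  bloodCalled <- !is.na(fam$blood_called) & fam$blood_called
  spermCalled <- !is.na(fam$sperm_called) & fam$sperm_called &
    fam$parental_origin == "paternal"

  getMaf <- function(fid, person, tissue) {
    v <- mdd$maf[mdd$family_id == fid & mdd$person == person &
                 mdd$tissue == tissue]
    if (length(v)) v[1L] else NA_real_
  }
  peripheral <- c("oral_epithelium", "saliva", "hair_follicle", "urine")

  undetectable <- if ("sanger_screening" %in% names(fam))
    fam$sanger_screening == "undetectable" else rep(FALSE, nrow(fam))

  tissueMafs <- unlist(lapply(which(!is.na(fam$mosaic_parent)), function(i)
    vapply(peripheral, getMaf, numeric(1L), fid = fam$family_id[i],
           person = fam$mosaic_parent[i])))
  tissueMafs <- tissueMafs[!is.na(tissueMafs)]

  # fathers with a sperm measurement and >= 1 other peripheral tissue
  fathers <- fam[fam$parental_origin == "paternal", , drop = FALSE]
  spermHighest <- vapply(fathers$family_id, function(fid) {
    sp <- getMaf(fid, "father", "sperm")
    other <- vapply(peripheral, getMaf, numeric(1L), fid = fid,
                    person = "father")
    other <- other[!is.na(other)]
    if (is.na(sp) || !length(other)) return(NA)
    all(sp > other)
  }, logical(1L))

  mothers <- fam[fam$parental_origin == "maternal", , drop = FALSE]
  bloodHighest <- vapply(mothers$family_id, function(fid) {
    bl <- getMaf(fid, "mother", "blood")
    other <- vapply(peripheral, getMaf, numeric(1L), fid = fid,
                    person = "mother")
    other <- other[!is.na(other)]
    if (is.na(bl) || !length(other)) return(NA)
    all(bl > other)
  }, logical(1L))

  spermMafs <- vapply(fam$family_id[spermCalled], getMaf, numeric(1L),
                      person = "father", tissue = "sperm")
  bloodMafs <- vapply(which(bloodCalled & !is.na(fam$mosaic_parent)),
                      function(i) getMaf(fam$family_id[i],
                                         fam$mosaic_parent[i], "blood"),
                      numeric(1L))
  rangeOrNA <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) range(v) else c(NA_real_, NA_real_)
  }
  new("CohortSummary",
      nBloodMosaic = sum(bloodCalled),
      nSpermMosaic = sum(spermCalled),
      nSpermOnly = sum(spermCalled & !bloodCalled),
      nPaternal = sum(fam$parental_origin == "paternal"),
      nMaternal = sum(fam$parental_origin == "maternal"),
      nSangerUndetectableBloodMosaic = sum(bloodCalled & undetectable),
      nTissueSamples = length(tissueMafs),
      nTissuePositive = sum(tissueMafs > 0),
      fathersSpermHighest = c(sum(spermHighest, na.rm = TRUE),
                              sum(!is.na(spermHighest))),
      mothersBloodHighest = c(sum(bloodHighest, na.rm = TRUE),
                              sum(!is.na(bloodHighest))),
      spermMafRange = rangeOrNA(spermMafs),
      bloodMafRange = rangeOrNA(bloodMafs))
})
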