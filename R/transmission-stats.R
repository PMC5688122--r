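#' Paired blood/sperm MAFs of the mosaic fathers
#'
#' Extracts, from a cohort, the paternal-origin families in which the
#' father donated a sperm sample and carries the mosaicism in at least one
#' compartment: one row per father with his blood and sperm MAFs (mDDPCR,
#' corrected scale) and the larger/smaller of the two. Fathers of
#' maternal-origin families are excluded even when their semen was assayed
#' (they are not carriers of the transmitted mosaic allele).
#'
#' @param cohort a [CohortTable-class].
#' @return data.frame with columns `family_id`, `maf_blood`, `maf_sperm`,
#'   `maf_large`, `maf_small`.
#' @examples
#' transmissionPairs(table1Fixture())
#' @export
transmissionPairs <- function(cohort) {
  stopifnot(is(cohort, "CohortTable"))
  fam <- families(cohort)
  smp <- samples(cohort)
  paternal <- fam$family_id[fam$parental_origin == "paternal"]
  pick <- function(fid, tissue) {
    v <- smp$maf[smp$family_id == fid & smp$person == "father" &
                 smp$tissue == tissue & smp$platform == "mDDPCR"]
    if (length(v)) v[1L] else NA_real_
  }
  rows <- lapply(paternal, function(fid) {
    sp <- pick(fid, "sperm")
    bl <- pick(fid, "blood")
    if (is.na(sp)) return(NULL)  # no semen sample donated
    if (max(sp, bl, na.rm = TRUE) == 0) return(NULL)
    data.frame(family_id = fid, maf_blood = bl, maf_sperm = sp,
               maf_large = max(bl, sp), maf_small = min(bl, sp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family_id = character(), maf_blood = numeric(),
                      maf_sperm = numeric(), maf_large = numeric(),
                      maf_small = numeric())
  out
}

#' Per-father transmission-conditioned probability
#'
#' For one father with MAFs measured in blood and sperm, the probability of
#' observing the sperm-vs-blood ordering that was seen, conditional on the
#' mutant allele having been transmitted to the affected child. Under equal
#' prior odds for the two orderings, Bayes' rule reduces this to
#' `MAF_large / (MAF_large + MAF_small)`: transmission is proportionally
#' more likely to have come from the compartment with the larger mutant
#' fraction, so conditioning on it tempers the evidence that sperm MAFs
#' exceed blood MAFs.
#'
#' @param mafBlood,mafSperm paired fractions (vectorised); at least one of
#'   each pair must be positive.
#' @return Probabilities in (0, 1].
#' @examples
#' conditionalTerm(0.2859, 0.3904)  # 0.577
#' @export
conditionalTerm <- function(mafBlood, mafSperm) {
  stopifnot(length(mafBlood) == length(mafSperm))
  if (any(is.na(mafBlood) | is.na(mafSperm)))
    stop("missing MAF in a transmission pair")
  if (any(mafBlood == 0 & mafSperm == 0))
    stop("both MAFs zero: conditional term undefined")
  large <- pmax(mafBlood, mafSperm)
  small <- pmin(mafBlood, mafSperm)
  large / (large + small)
}

#' Transmission-corrected one-tailed probability
#'
#' The probability of observing the sperm-vs-blood MAF ordering in every
#' father, given that each father transmitted the mutant allele to his
#' affected child: the product over fathers of [conditionalTerm()]. This is
#' the transmission-conditioned one-tailed p-value for sperm MAFs exceeding
#' blood MAFs across the cohort.
#'
#' @param pairs data.frame from [transmissionPairs()] (or any data.frame
#'   with `maf_blood` and `maf_sperm` columns).
#' @return A single probability.
#' @examples
#' correctedTransmissionP(transmissionPairs(table1Fixture()))
#' @export
correctedTransmissionP <- function(pairs) {
  stopifnot(all(c("maf_blood", "maf_sperm") %in% names(pairs)))
  if (nrow(pairs) == 0L) {
    warning("no transmission pairs: returning the vacuous product 1")
    return(1)
  }
  degenerate <- pairs$maf_blood == 0 & pairs$maf_sperm == 0
  if (any(degenerate)) {
    warning(sprintf("dropping %d pair(s) with MAF zero in both compartments",
                    sum(degenerate)))
    pairs <- pairs[!degenerate, , drop = FALSE]
    if (nrow(pairs) == 0L) return(1)
  }
  prod(conditionalTerm(pairs$maf_blood, pairs$maf_sperm))
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test for paired measurements, defaulting to the exact null
#' distribution (all `2^m` sign assignments of the `m` nonzero differences)
#' when `m <= 25` and the absolute differences are tie-free; otherwise the
#' normal approximation with continuity correction is used. Zero
#' differences are dropped.
#'
#' @param x,y paired numeric vectors.
#' @param alternative `"greater"` (x tends to exceed y), `"less"` or
#'   `"two.sided"`.
#' @param mode `"auto"` (default), `"exact"` or `"normal_cc"`.
#' @return A list with `p.value`, `statistic` (V, the positive-rank sum),
#'   `m` (nonzero differences) and `mode` actually used.
#' @examples
#' pr <- transmissionPairs(table1Fixture())
#' pairedWilcoxon(pr$maf_sperm, pr$maf_blood, alternative = "greater")
#' @export
pairedWilcoxon <- function(x, y,
                           alternative = c("two.sided", "greater", "less"),
                           mode = c("auto", "exact", "normal_cc")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  m <- sum(d != 0)
  if (m == 0L) stop("all paired differences are zero")
  ties <- anyDuplicated(abs(d[d != 0])) > 0L
  if (mode == "auto") mode <- if (m <= 25L && !ties) "exact" else "normal_cc"
  if (mode == "exact" && ties)
    stop("ties in |differences|: the exact distribution is not available")
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, paired = TRUE, alternative = alternative,
    exact = (mode == "exact"), correct = TRUE))
  list(p.value = ht$p.value, statistic = unname(ht$statistic), m = m,
       mode = mode)
}

#' Regression of sperm on blood MAFs on the square-root scale
#'
#' Ordinary least squares of `sqrt(maf_sperm)` on `sqrt(maf_blood)`. The
#' square-root transform stabilises the variance of small fractions and
#' linearises the sperm-blood relation, so a positive slope quantifies how
#' reliably an elevated sperm MAF accompanies a blood MAF.
#'
#' @param mafBlood,mafSperm paired fractions.
#' @param conf level for the confidence and prediction bands, default 0.95.
#' @return A list with `slope`, `intercept`, `rSquared`, `fPvalue`, `n`,
#'   the `lm` `fit`, and `bands`: a data.frame of fitted values with
#'   confidence and prediction intervals (on the sqrt scale) at each
#'   observed blood MAF.
#' @examples
#' pr <- transmissionPairs(table1Fixture())
#' sqrtMafRegression(pr$maf_blood, pr$maf_sperm)$rSquared
#' @export
sqrtMafRegression <- function(mafBlood, mafSperm, conf = 0.95) {
  stopifnot(length(mafBlood) == length(mafSperm))
  ok <- !is.na(mafBlood) & !is.na(mafSperm)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  df <- data.frame(sb = sqrt(mafBlood[ok]), ss = sqrt(mafSperm[ok]))
  fit <- stats::lm(ss ~ sb, data = df)
  sm <- summary(fit)
  f <- sm$fstatistic
  grid <- df[order(df$sb), "sb", drop = FALSE]
  ci <- stats::predict(fit, grid, interval = "confidence", level = conf)
  pi <- stats::predict(fit, grid, interval = "prediction", level = conf)
  bands <- data.frame(sqrt_blood = grid$sb, fit = ci[, "fit"],
                      ci_low = ci[, "lwr"], ci_high = ci[, "upr"],
                      pi_low = pi[, "lwr"], pi_high = pi[, "upr"])
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       rSquared = sm$r.squared,
       fPvalue = unname(stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE)),
       n = nrow(df), fit = fit, bands = bands)
}
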