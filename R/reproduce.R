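#' Quantify droplet runs from a counts file
#'
#' Reads a TSV of gated droplet counts (columns `sample_id`, `n_mutant`,
#' `n_wildtype`, `n_double`, `n_empty`), estimates each sample's MAF with
#' its exact 95% CI, applies the assay's homology correction and calling
#' rule, and returns the per-sample call table. Provenance (threshold,
#' copy count, package version) is attached as attributes.
#'
#' @param path droplet-count TSV.
#' @param assay an [AssayConfig-class].
#' @param lambdaCorrect passed to [estimateMaf()].
#' @return data.frame with one row per sample: raw and corrected MAF, CI
#'   bounds and call.
#' @export
quantifyDroplets <- function(path, assay = AssayConfig(),
                             lambdaCorrect = FALSE) {
  stopifnot(is(assay, "AssayConfig"))
  counts <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  need <- c("sample_id", "n_mutant", "n_wildtype", "n_double", "n_empty")
  if (!all(need %in% names(counts)))
    stop(sprintf("droplet file must have columns %s",
                 paste(need, collapse = ", ")))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    dc <- DropletCounts(counts$n_mutant[i], counts$n_wildtype[i],
                        counts$n_double[i], counts$n_empty[i])
    est <- estimateMaf(dc, lambdaCorrect = lambdaCorrect)
    est <- correctHomology(est, assay@homologyCopies)
    est <- callSample(est, assay)
    data.frame(sample_id = counts$sample_id[i], maf_raw = est@maf,
               ci_low_raw = est@ciLow, ci_high_raw = est@ciHigh,
               maf = est@mafCorrected, ci_low = est@ciLowCorrected,
               ci_high = est@ciHighCorrected, call = est@call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "detectThreshold") <- assay@detectThreshold
  attr(out, "homologyCopies") <- assay@homologyCopies
  attr(out, "package_version") <-
    as.character(utils::packageVersion("mosaicDDPCR"))
  out
}

#' Recompute the headline cohort statistics from the packaged data
#'
#' Runs the whole analysis on [table1Fixture()] and returns the headline
#' quantities: the paired exact one-tailed Wilcoxon p for sperm > blood in
#' the 10 mosaic fathers, the transmission-conditioned corrected
#' probability, the parent-of-origin exact binomial p, the sperm-on-blood
#' square-root regression R^2 and F-test p, the cohort census counts, and
#' the mosaic-father vs mosaic-mother epilepsy comparison (from the
#' published per-sex epilepsy fractions, 8/18 fathers and 4/11 mothers).
#'
#' @return data.frame with columns `quantity` and `value`; package version
#'   attached as an attribute.
#' @examples
#' reproducePaper()
#' @export
reproducePaper <- function() {
  cohort <- table1Fixture()
  pairs <- transmissionPairs(cohort)
  wil <- pairedWilcoxon(pairs$maf_sperm, pairs$maf_blood,
                        alternative = "greater")
  reg <- sqrtMafRegression(pairs$maf_blood, pairs$maf_sperm)
  smry <- summarizeCohort(cohort)
  fish <- fisherExact(8, 10, 4, 7)
  origin <- exactBinomialTest(smry@nPaternal, smry@nPaternal + smry@nMaternal)
  out <- data.frame(
    quantity = c("sperm_vs_blood_wilcoxon_p", "transmission_corrected_p",
                 "parent_origin_binomial_p", "sqrt_regression_r_squared",
                 "sqrt_regression_f_p", "n_transmission_pairs",
                 "n_blood_mosaic", "n_sperm_mosaic", "n_sperm_only",
                 "n_sanger_undetectable_blood_mosaic", "n_tissue_samples",
                 "n_tissue_positive", "fathers_sperm_highest_k",
                 "fathers_sperm_highest_n", "mothers_blood_highest_k",
                 "mothers_blood_highest_n", "sperm_maf_min_percent",
                 "sperm_maf_max_percent", "epilepsy_sex_sample_or",
                 "epilepsy_sex_fisher_p"),
    value = c(wil$p.value, correctedTransmissionP(pairs), origin,
              reg$rSquared, reg$fPvalue, nrow(pairs),
              smry@nBloodMosaic, smry@nSpermMosaic, smry@nSpermOnly,
              smry@nSangerUndetectableBloodMosaic, smry@nTissueSamples,
              smry@nTissuePositive, smry@fathersSpermHighest[1L],
              smry@fathersSpermHighest[2L], smry@mothersBloodHighest[1L],
              smry@mothersBloodHighest[2L], 100 * smry@spermMafRange[1L],
              100 * smry@spermMafRange[2L], fish$sampleOR, fish$p.value),
    stringsAsFactors = FALSE)
  attr(out, "package_version") <-
    as.character(utils::packageVersion("mosaicDDPCR"))
  out
}
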